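## Exponential decay fitting and the derived relaxation observables:
## R1, R1rho, off-resonance-corrected R2, heteronuclear NOE.

#' Fit a mono-exponential decay
#'
#' Least-squares fit of `I(x) = I0 * exp(-rate * x)` to an intensity series
#' (relaxation delay series for R1/R1rho, squared-gradient series for
#' diffusion). Parameter errors come from the fit covariance; the root mean
#' square deviation of the residuals is reported for ranking fits.
#'
#' @param x independent variable (>= 3 distinct values).
#' @param intensity observed intensities (not all zero).
#' @param err optional per-point intensity errors used as weights.
#' @param data alternatively, a data.frame with columns `x`, `intensity`
#'   and optionally `err` (as produced by [gen_relaxation_decays()]).
#' @return object of class `"decay_fit"`: list with `rate`, `rate_err`,
#'   `i0`, `i0_err`, `rmsd`, `negative_rate` flag and the data. Methods:
#'   `print`, `coef`, `predict`, `residuals`.
#' @export
fit_exponential <- function(x, intensity, err = NULL, data = NULL) {
  if (!is.null(data)) {
    x <- data$x; intensity <- data$intensity; err <- data$err
  }
  keep <- is.finite(x) & is.finite(intensity)
  x <- x[keep]; intensity <- intensity[keep]
  if (!is.null(err)) err <- rep_len(err, length(keep))[keep]
  if (length(unique(x)) < 3) stop("need at least 3 distinct x values")
  if (all(intensity == 0)) stop("intensities are all zero")
  w <- if (is.null(err) || !all(is.finite(err)) || any(err <= 0)) {
    rep(1, length(x))
  } else 1 / err^2

  ## log-linear initialisation on the positive part
  pos <- intensity > 0
  r0 <- if (sum(pos) >= 2) {
    cf <- stats::coef(stats::lm(log(intensity[pos]) ~ x[pos]))
    max(-cf[2], 0)
  } else 0
  i0_0 <- max(abs(intensity))

  fit <- tryCatch(
    minpack.lm::nlsLM(intensity ~ i0 * exp(-rate * x),
                      start = list(i0 = i0_0, rate = r0),
                      weights = w,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("exponential fit did not converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) c(i0 = NA_real_, rate = NA_real_))
  resid <- intensity - cf[["i0"]] * exp(-cf[["rate"]] * x)
  negative <- cf[["rate"]] < 0
  if (negative) warning("best-fit rate is negative; reported as is")
  out <- list(rate = cf[["rate"]], rate_err = unname(se["rate"]),
              i0 = cf[["i0"]], i0_err = unname(se["i0"]),
              rmsd = sqrt(mean(resid^2)),
              negative_rate = negative,
              data = data.frame(x = x, intensity = intensity),
              call = match.call())
  class(out) <- "decay_fit"
  out
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Exponential decay fit: rate = %.4g +/- %.2g, I0 = %.4g, RMSD = %.3g\n",
              x$rate, x$rate_err, x$i0, x$rmsd))
  if (x$negative_rate) cat("  (warning: negative best-fit rate)\n")
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) {
  c(i0 = object$i0, rate = object$rate)
}

#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else {
    if (is.list(newdata)) newdata$x else newdata
  }
  object$i0 * exp(-object$rate * x)
}

#' @export
residuals.decay_fit <- function(object, ...) {
  object$data$intensity - predict(object)
}

#' Transverse rate from rotating-frame relaxation
#'
#' Off-resonance tilted-frame correction
#' `R2 = R1rho / sin^2(theta) - R1 / tan^2(theta)`, where `theta` is the
#' tilt angle of the effective spin-lock field. For an on-resonance spin
#' lock (`theta = 90` degrees) this reduces to `R2 = R1rho`.
#'
#' @param r1rho rotating-frame rate, s^-1 (numeric or a `decay_fit`).
#' @param r1 longitudinal rate, s^-1 (numeric or a `decay_fit`).
#' @param theta tilt angle in degrees, 0 < theta <= 90 (default 90).
#' @return R2 in s^-1.
#' @export
derive_r2 <- function(r1rho, r1, theta = 90) {
  if (inherits(r1rho, "decay_fit")) r1rho <- r1rho$rate
  if (inherits(r1, "decay_fit")) r1 <- r1$rate
  if (any(theta <= 0) || any(theta > 90)) {
    stop("tilt angle theta must satisfy 0 < theta <= 90 degrees")
  }
  if (any(theta < 1e-3)) stop("tilt angle too close to zero: R2 diverges")
  th <- theta * pi / 180
  ifelse(theta == 90, r1rho, r1rho / sin(th)^2 - r1 / tan(th)^2)
}

#' Steady-state heteronuclear NOE
#'
#' Ratio of peak intensities with and without proton saturation; the error
#' is propagated from the two intensity errors in quadrature. Negative
#' ratios (flexible termini) are valid output.
#'
#' @param i_sat intensity with proton saturation.
#' @param i_ref intensity without saturation (non-zero).
#' @param i_sat_err,i_ref_err intensity errors.
#' @return data.frame with `noe` and `noe_err`.
#' @export
het_noe <- function(i_sat, i_ref, i_sat_err = 0, i_ref_err = 0) {
  if (any(i_ref == 0)) stop("reference intensity must be non-zero")
  noe <- i_sat / i_ref
  err <- sqrt((i_sat_err / i_ref)^2 + (i_sat * i_ref_err / i_ref^2)^2)
  data.frame(noe = noe, noe_err = err)
}
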