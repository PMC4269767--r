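## Lipari-Szabo model-free analysis of backbone amide 15N relaxation:
## spectral density, back-calculation of (R1, R2, NOE), global rotational
## correlation time from trimmed R2/R1 ratios, and per-residue S2/tau_e
## fitting with F-test model selection.

#' Lipari-Szabo spectral density
#'
#' `J(w) = (2/5) * (S2*tc/(1+(w tc)^2) + (1-S2)*t/(1+(w t)^2))` with
#' `1/t = 1/tc + 1/te`. `J` is even in `w`, non-negative, and monotone
#' non-increasing in `|w|`.
#'
#' @param omega angular frequency, rad/s (vectorised).
#' @param s2 order parameter in `[0, 1]`.
#' @param tau_c overall rotational correlation time, s.
#' @param tau_e internal correlation time, s (>= 0).
#' @return spectral density in s/rad.
#' @export
spectral_density <- function(omega, s2, tau_c, tau_e = 0) {
  stopifnot(all(s2 >= 0), all(s2 <= 1), all(tau_c > 0), all(tau_e >= 0))
  tau <- tau_c * tau_e / (tau_c + tau_e)  # 0 when tau_e = 0
  0.4 * (s2 * tau_c / (1 + (omega * tau_c)^2) +
           (1 - s2) * tau / (1 + (omega * tau)^2))
}

## dipolar and CSA interaction constants for the 15N-1H pair
.mf_constants <- function(field_mhz) {
  wh <- 2 * pi * field_mhz * 1e6
  wn <- wh * .n15_fraction
  d <- .nmr$mu0 / (4 * pi) * .nmr$hbar * .nmr$gamma_H * abs(.nmr$gamma_N) /
    .nmr$r_NH^3
  list(wh = wh, wn = wn, d2 = d^2, c2 = (wn * abs(.nmr$csa_N))^2 / 3)
}

#' Back-calculate 15N relaxation rates from model-free parameters
#'
#' Standard 15N dipolar/CSA expressions: linear combinations of the
#' spectral density at `{0, wN, wH, wH +/- wN}` with the dipolar constant
#' from a 1.02 A N-H bond and a -160 ppm 15N CSA.
#'
#' @param s2 order parameter (vectorised).
#' @param tau_c_ns rotational correlation time, ns.
#' @param tau_e_ps internal correlation time, ps (vectorised).
#' @param field_mhz static field as 1H Larmor frequency, MHz.
#' @return data.frame with columns `r1`, `r2` (s^-1) and `noe` (ratio).
#' @export
predict_rates <- function(s2, tau_c_ns, tau_e_ps, field_mhz) {
  stopifnot(all(field_mhz > 0))
  m <- max(length(s2), length(tau_e_ps), length(field_mhz))
  s2 <- rep_len(s2, m); tau_e <- rep_len(tau_e_ps, m) * 1e-12
  field_mhz <- rep_len(field_mhz, m)
  tc <- tau_c_ns * 1e-9
  k <- .mf_constants(field_mhz)
  J <- function(w) spectral_density(w, s2, tc, tau_e)
  j0 <- J(0); jn <- J(k$wn); jh <- J(k$wh)
  jhmn <- J(k$wh - k$wn); jhpn <- J(k$wh + k$wn)
  r1 <- k$d2 / 4 * (jhmn + 3 * jn + 6 * jhpn) + k$c2 * jn
  r2 <- k$d2 / 8 * (4 * j0 + jhmn + 3 * jn + 6 * jh + 6 * jhpn) +
    k$c2 / 6 * (4 * j0 + 3 * jn)
  sigma <- k$d2 / 4 * (6 * jhpn - jhmn)
  # degenerate corner (all J = 0, hence R1 = 0): no cross-relaxation
  noe <- ifelse(r1 > 0, 1 + (.nmr$gamma_H / .nmr$gamma_N) * sigma / r1, 1)
  data.frame(r1 = r1, r2 = r2, noe = noe)
}

#' Global rotational correlation time from R2/R1 ratios
#'
#' Estimates the isotropic rotational correlation time from the trimmed
#' mean of per-residue R2/R1 ratios of rigid residues (heteronuclear NOE
#' above `noe_cutoff`), by matching the ratio predicted for a rigid rotor.
#' The R2/R1 ratio of the simple Lipari-Szabo model is independent of S2
#' when internal motion is fast, and trimming discards residues whose R2 is
#' inflated by chemical exchange or deflated by slow internal motion.
#'
#' @param rates data.frame with columns `residue`, `field`, `r1`, `r2`,
#'   `noe` (as from [gen_modelfree_rates()]).
#' @param noe_cutoff rigidity cutoff on the NOE (default 0.65).
#' @param trim fraction trimmed from each tail of the ratio distribution.
#' @param interval_ns search interval for tau_c, ns.
#' @param refine if `TRUE`, polish the ratio estimate by minimising the
#'   total per-residue model-free chi-square as a function of tau_c (the
#'   global-correlation-time strategy of model-free software). The plain
#'   ratio estimator is biased slightly low when fast internal motion
#'   contributes to the rates; the refinement removes that bias at the
#'   cost of extra fits.
#' @return list with `tau_c_ns`, `n_used`, per-field observed and
#'   predicted ratios (and `tau_c_ratio_ns`, the unrefined estimate, when
#'   `refine = TRUE`).
#' @export
fit_tc <- function(rates, noe_cutoff = 0.65, trim = 0.25,
                   interval_ns = c(0.5, 30), refine = FALSE) {
  stopifnot(all(c("residue", "field", "r1", "r2", "noe") %in% names(rates)))
  ok <- is.finite(rates$r1) & is.finite(rates$r2) & is.finite(rates$noe) &
    rates$noe >= noe_cutoff & rates$r1 > 0
  if (sum(ok) < 5) stop("fewer than 5 rigid residues with complete R1, R2")
  d <- rates[ok, ]
  fields <- sort(unique(d$field))
  obs <- vapply(fields, function(f) {
    mean(d$r2[d$field == f] / d$r1[d$field == f], trim = trim)
  }, numeric(1))
  objective <- function(tc_ns) {
    pred <- vapply(fields, function(f) {
      p <- predict_rates(1, tc_ns, 0, f)
      p$r2 / p$r1
    }, numeric(1))
    sum((pred - obs)^2)
  }
  opt <- stats::optimize(objective, interval_ns, tol = 1e-10)
  pred <- vapply(fields, function(f) {
    p <- predict_rates(1, opt$minimum, 0, f)
    p$r2 / p$r1
  }, numeric(1))
  out <- list(tau_c_ns = opt$minimum, n_used = sum(ok),
              fields = fields, ratio_obs = obs, ratio_pred = pred)
  if (refine) {
    sp <- split(d, d$residue)
    o2 <- stats::optimize(function(tc) .mf_total_chi2(sp, tc),
                          c(max(interval_ns[1], opt$minimum - 1.5),
                            min(interval_ns[2], opt$minimum + 1.5)),
                          tol = 1e-4)
    out$tau_c_ratio_ns <- out$tau_c_ns
    out$tau_c_ns <- o2$minimum
  }
  out
}

## weighted chi-square of one residue's (R1, R2, NOE) set against the
## model-free prediction, as a function of (S2, tau_e); relative weights
## when no errors are available
.mf_chi2_fun <- function(d, tau_c_ns) {
  y <- c(d$r1, d$r2, d$noe)
  err <- c(d$r1_err %||% rep(NA, nrow(d)),
           d$r2_err %||% rep(NA, nrow(d)),
           d$noe_err %||% rep(NA, nrow(d)))
  w <- if (all(is.finite(err)) && all(err > 0)) 1 / err^2 else 1 / y^2
  function(s2, te_ps) {
    p <- predict_rates(s2, tau_c_ns, te_ps, d$field)
    sum(w * (c(p$r1, p$r2, p$noe) - y)^2)
  }
}

## total best-fit chi-square over residues at a trial tau_c (extended
## model, two tau_e starts); used by the fit_tc refinement
.mf_total_chi2 <- function(split_rates, tau_c_ns, tau_e_max_ps = 5000) {
  total <- 0
  for (d in split_rates) {
    chi2 <- .mf_chi2_fun(d, tau_c_ns)
    o1 <- stats::optimize(function(s) chi2(s, 0), c(0, 1), tol = 1e-9)
    best <- o1$objective
    for (te0 in c(20, 200)) {
      o <- stats::optim(c(min(max(o1$minimum, 1e-3), 1 - 1e-3), te0),
                        function(p) chi2(p[1], p[2]),
                        method = "L-BFGS-B",
                        lower = c(0, 0), upper = c(1, tau_e_max_ps),
                        control = list(factr = 1e5))
      best <- min(best, o$value)
    }
    total <- total + best
  }
  total
}

#' Per-residue model-free fit
#'
#' With the global rotational correlation time fixed (from [fit_tc()]),
#' fits each residue's (R1, R2, NOE) set by weighted least squares under
#' two nested models: S2 only, and S2 plus an internal correlation time
#' tau_e. The extended model is retained when an F-test prefers it at
#' level `alpha`. S2 is constrained to `[0, 1]`; hitting the boundary is
#' flagged. Exchange broadening is deliberately not a model parameter here:
#' residues with dispersion-detected exchange belong to the CPMG analysis.
#'
#' @param rates data.frame with columns `residue`, `field`, `r1`, `r2`,
#'   `noe` and optionally `r1_err`, `r2_err`, `noe_err` (used as weights;
#'   relative weights are used when absent).
#' @param tau_c_ns global rotational correlation time, ns.
#' @param alpha F-test level for adding tau_e (default 0.05).
#' @param tau_e_max_ps upper bound of the tau_e search, ps.
#' @return object of class `"modelfree_fit"`: `tau_c_ns` and a per-residue
#'   data.frame (`residue`, `s2`, `s2_err`, `tau_e_ps`, `model`, `chi2`,
#'   `boundary`). Methods: `print`, `coef`, `predict`.
#' @export
fit_modelfree <- function(rates, tau_c_ns, alpha = 0.05,
                          tau_e_max_ps = 5000) {
  stopifnot(all(c("residue", "field", "r1", "r2", "noe") %in% names(rates)))
  res_lev <- sort(unique(rates$residue))
  fields <- sort(unique(rates$field))
  n_obs <- 3 * length(fields)

  fit_one <- function(d) {
    chi2 <- .mf_chi2_fun(d, tau_c_ns)
    o1 <- stats::optimize(function(s) chi2(s, 0), c(0, 1), tol = 1e-10)
    best2 <- NULL
    for (te0 in c(10, 50, 200, 1000)) {
      o <- stats::optim(c(min(max(o1$minimum, 1e-3), 1 - 1e-3), te0),
                        function(p) chi2(p[1], p[2]),
                        method = "L-BFGS-B",
                        lower = c(0, 0), upper = c(1, tau_e_max_ps),
                        control = list(factr = 1e4))
      if (is.null(best2) || o$value < best2$value) best2 <- o
    }
    chi1 <- o1$objective; chi2v <- best2$value
    df2 <- n_obs - 2
    use_ext <- FALSE
    if (df2 > 0 && chi1 > 1e-12) {
      Fst <- if (chi2v <= 0) Inf else (chi1 - chi2v) / (chi2v / df2)
      use_ext <- is.finite(Fst) &&
        stats::pf(Fst, 1, df2, lower.tail = FALSE) < alpha ||
        !is.finite(Fst)
    }
    if (use_ext) {
      s2 <- best2$par[1]; te <- best2$par[2]; chi <- chi2v; mod <- "s2_te"
    } else {
      s2 <- o1$minimum; te <- 0; chi <- chi1; mod <- "s2"
    }
    ## curvature-based S2 error (finite differences on chi2)
    h <- 1e-4
    s2m <- min(max(s2, h), 1 - h)
    curv <- (chi2(s2m + h, te) - 2 * chi2(s2m, te) + chi2(s2m - h, te)) / h^2
    s2_err <- if (is.finite(curv) && curv > 0) sqrt(2 / curv) else NA_real_
    boundary <- s2 > 1 - 1e-4 || s2 < 1e-4
    ## snap to the boundary when the optimizer stops just inside it
    if (s2 > 1 - 1e-4 && chi2(1, te) <= chi + 1e-10) s2 <- 1
    data.frame(s2 = s2, s2_err = s2_err, tau_e_ps = te, model = mod,
               chi2 = chi, boundary = boundary)
  }

  tabs <- lapply(res_lev, function(r) {
    d <- rates[rates$residue == r, ]
    out <- tryCatch(fit_one(d), error = function(e) {
      warning("model-free fit failed for residue ", r, ": ",
              conditionMessage(e))
      data.frame(s2 = NA_real_, s2_err = NA_real_, tau_e_ps = NA_real_,
                 model = "failed", chi2 = NA_real_, boundary = NA)
    })
    cbind(residue = r, out)
  })
  out <- list(tau_c_ns = tau_c_ns, residues = do.call(rbind, tabs),
              fields = fields, alpha = alpha, call = match.call())
  class(out) <- "modelfree_fit"
  out
}

#' @export
print.modelfree_fit <- function(x, ...) {
  r <- x$residues
  cat(sprintf("Model-free fit: tau_c = %.2f ns, %d residues (fields: %s MHz)\n",
              x$tau_c_ns, nrow(r), paste(x$fields, collapse = "/")))
  ok <- is.finite(r$s2)
  cat(sprintf("  S2: median %.3f, range %.3f-%.3f; %d residue(s) with tau_e > 0\n",
              stats::median(r$s2[ok]), min(r$s2[ok]), max(r$s2[ok]),
              sum(r$tau_e_ps > 0, na.rm = TRUE)))
  invisible(x)
}

#' @export
coef.modelfree_fit <- function(object, ...) {
  stats::setNames(object$residues$s2, object$residues$residue)
}

#' @export
predict.modelfree_fit <- function(object, field_mhz = object$fields, ...) {
  r <- object$residues
  do.call(rbind, lapply(field_mhz, function(f) {
    cbind(residue = r$residue, field = f,
          predict_rates(r$s2, object$tau_c_ns, r$tau_e_ps, f))
  }))
}

#' Sliding-window average of a per-residue profile
#'
#' Mean over residues within `+/- half_width` sequence positions of each
#' residue (used to display smoothed order-parameter profiles).
#'
#' @param residue residue numbers.
#' @param value per-residue values (e.g. S2).
#' @param half_width window half width in residues (default 2).
#' @return vector of windowed means aligned with `residue`.
#' @export
sliding_mean <- function(residue, value, half_width = 2) {
  vapply(residue, function(r) {
    sel <- abs(residue - r) <= half_width & is.finite(value)
    mean(value[sel])
  }, numeric(1))
}
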