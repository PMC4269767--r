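## Chemical-shift analytics: cumulative shift differences across up to five
## backbone nuclei, combined amide CSPs, single-site Kd fits of CSP
## titrations, and the dispersion-versus-binding shift correlation.

#' Default per-nucleus shift normalisation factors
#'
#' One standard deviation of the chemical-shift distribution of each
#' backbone nucleus, as observed across deposited protein assignments
#' (approximate BMRB-derived values, ppm). Shipped as a fixed table so the
#' analysis is reproducible without database access; users may override.
#'
#' @format named numeric vector with elements `h`, `n`, `co`, `ca`, `cb`.
#' @export
bmrb_shift_sd <- c(h = 0.65, n = 4.7, co = 1.8, ca = 2.6, cb = 5.3)

.shift_nuclei <- c("h", "n", "co", "ca", "cb")

#' Cumulative chemical shift difference between two states
#'
#' For each residue, `dw_cum = sqrt((1/N) * sum_i (dw_i / w_i,std)^2)`
#' where the sum runs over the nuclei (1HN, 15N, 13C', 13Ca, 13Cb) whose
#' shifts are available in both tables, `N` (<= 5) is their count, and
#' `w_i,std` is the per-nucleus normalisation factor. Residues with no
#' shared nucleus are dropped with a message.
#'
#' @param apo,bound shift tables: data.frames with column `residue` and
#'   any of `h`, `n`, `co`, `ca`, `cb` (ppm; NA = missing).
#' @param std per-nucleus normalisation factors (positive), default
#'   [bmrb_shift_sd].
#' @return data.frame (`residue`, `n_nuclei`, `dw_cum`).
#' @export
delta_omega_cum <- function(apo, bound, std = bmrb_shift_sd) {
  stopifnot("residue" %in% names(apo), "residue" %in% names(bound),
            all(std > 0))
  nuc <- intersect(.shift_nuclei, intersect(names(apo), names(bound)))
  if (length(nuc) == 0) stop("no shift columns shared between the tables")
  if (!all(nuc %in% names(std))) stop("std lacks a factor for some nucleus")
  m <- merge(apo[, c("residue", nuc)], bound[, c("residue", nuc)],
             by = "residue", suffixes = c("_a", "_b"))
  out <- data.frame(residue = m$residue, n_nuclei = 0L, dw_cum = NA_real_)
  ss <- matrix(NA_real_, nrow(m), length(nuc))
  for (j in seq_along(nuc)) {
    da <- m[[paste0(nuc[j], "_a")]]
    db <- m[[paste0(nuc[j], "_b")]]
    ss[, j] <- ((db - da) / std[nuc[j]])^2
  }
  out$n_nuclei <- rowSums(!is.na(ss))
  out$dw_cum <- sqrt(rowMeans(ss, na.rm = TRUE))
  none <- out$n_nuclei == 0
  if (any(none)) {
    message(sum(none), " residue(s) without a shared nucleus dropped")
    out <- out[!none, ]
  }
  rownames(out) <- NULL
  out
}

#' Combined amide chemical shift perturbation
#'
#' `sqrt(dH^2 + (w * dN)^2)` with the conventional 15N weight
#' `w = 0.154` reflecting the narrower 1H shift range.
#'
#' @param dh,dn 1H and 15N shift changes, ppm.
#' @param n_weight 15N weight (default 0.154).
#' @return combined CSP in ppm.
#' @export
combined_csp <- function(dh, dn, n_weight = 0.154) {
  sqrt(dh^2 + (n_weight * dn)^2)
}

#' Exact single-site binding isotherm
#'
#' Bound fraction of the protein for total ligand `L`, total protein `P`
#' and dissociation constant `Kd`:
#' `f = ((P + L + Kd) - sqrt((P + L + Kd)^2 - 4 P L)) / (2 P)`.
#'
#' @param ligand total ligand concentration (vectorised).
#' @param p_total total protein concentration.
#' @param kd dissociation constant, same unit.
#' @return bound fraction in `[0, 1]`.
#' @export
binding_fraction <- function(ligand, p_total, kd) {
  stopifnot(p_total > 0, kd > 0, all(ligand >= 0))
  s <- p_total + ligand + kd
  (s - sqrt(s^2 - 4 * p_total * ligand)) / (2 * p_total)
}

#' Fit a CSP titration for the dissociation constant
#'
#' Per residue, fits `CSP(L) = ddmax * f(L; P, Kd)` with the exact
#' quadratic isotherm ([binding_fraction()]) by nonlinear least squares;
#' optionally a single global Kd shared across residues (with per-residue
#' saturation CSPs profiled analytically, since they enter linearly).
#' Titrations that do not approach saturation are flagged.
#'
#' @param series titration data.frame (`residue`, `ligand`, `csp`) as from
#'   [gen_titration()]; at least 4 points including zero ligand.
#' @param p_total total protein concentration (same unit as `ligand`).
#' @param global if `TRUE`, additionally fit one shared Kd.
#' @return object of class `"kd_fit"`: per-residue table (`residue`, `kd`,
#'   `kd_err`, `ddmax`, `ddmax_err`, `f_max`, `saturation_flag`) plus
#'   `kd_global`/`kd_global_err` when requested. Methods: `print`, `coef`,
#'   `predict`.
#' @export
fit_kd <- function(series, p_total, global = FALSE) {
  stopifnot(all(c("residue", "ligand", "csp") %in% names(series)),
            p_total > 0)
  res_lev <- sort(unique(series$residue))
  lig0 <- sort(unique(series$ligand))
  if (length(lig0) < 4 || min(lig0) > 0) {
    stop("need >= 4 titration points including zero ligand")
  }

  fit_one <- function(d) {
    ## ddmax enters linearly: profile it and search Kd in 1-D on the log
    ## scale (robust in the tight-binding regime, where the isotherm
    ## gradient with respect to Kd is nearly singular)
    prof <- function(log_kd) {
      f <- binding_fraction(d$ligand, p_total, exp(log_kd))
      dd <- sum(f * d$csp) / sum(f^2)
      list(rss = sum((d$csp - dd * f)^2), ddmax = dd)
    }
    o <- stats::optimize(function(lk) prof(lk)$rss,
                         log(p_total) + log(c(1e-4, 1e3)), tol = 1e-12)
    kd <- exp(o$minimum)
    ddmax <- prof(o$minimum)$ddmax
    ## Gauss-Newton covariance at the optimum
    f <- binding_fraction(d$ligand, p_total, kd)
    h <- 1e-4
    dfdlk <- (binding_fraction(d$ligand, p_total, kd * exp(h)) -
                binding_fraction(d$ligand, p_total, kd * exp(-h))) / (2 * h)
    J <- cbind(f, ddmax * dfdlk)
    sigma2 <- o$objective / max(nrow(d) - 2, 1)
    cov <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
    se_dd <- if (is.null(cov)) NA_real_ else sqrt(cov[1, 1])
    se_kd <- if (is.null(cov)) NA_real_ else kd * sqrt(cov[2, 2])
    fmax <- binding_fraction(max(d$ligand), p_total, kd)
    flag <- fmax < 0.8
    if (flag) {
      warning("titration reaches only ", round(100 * fmax),
              "% saturation; Kd is poorly constrained")
    }
    data.frame(kd = kd, kd_err = se_kd, ddmax = ddmax, ddmax_err = se_dd,
               f_max = fmax, saturation_flag = flag)
  }

  tab <- do.call(rbind, lapply(res_lev, function(r) {
    cbind(residue = r, fit_one(series[series$residue == r, ]))
  }))
  rownames(tab) <- NULL

  kd_global <- NULL
  if (global) {
    ## ddmax enters linearly: profile it per residue for a given Kd
    rss <- function(log_kd) {
      f <- binding_fraction(series$ligand, p_total, exp(log_kd))
      sum(unlist(lapply(split(seq_len(nrow(series)), series$residue),
                        function(i) {
                          dd <- sum(f[i] * series$csp[i]) / sum(f[i]^2)
                          (series$csp[i] - dd * f[i])^2
                        })))
    }
    o <- stats::optimize(rss, log(c(p_total * 1e-4, p_total * 1e3)),
                         tol = 1e-12)
    ## quadratic curvature on log Kd for an approximate error
    h <- 1e-3
    curv <- (rss(o$minimum + h) - 2 * o$objective + rss(o$minimum - h)) / h^2
    n_free <- nrow(series) - length(res_lev) - 1
    sigma2 <- o$objective / max(n_free, 1)
    kd_global <- exp(o$minimum)
    kd_global_err <- if (is.finite(curv) && curv > 0) {
      kd_global * sqrt(2 * sigma2 / curv)
    } else NA_real_
  }

  out <- list(residues = tab, p_total = p_total,
              kd_global = if (global) kd_global else NULL,
              kd_global_err = if (global) kd_global_err else NULL,
              call = match.call())
  class(out) <- "kd_fit"
  out
}

#' @export
print.kd_fit <- function(x, ...) {
  ok <- is.finite(x$residues$kd)
  cat(sprintf("CSP titration fit: %d residue(s), median Kd = %.3g\n",
              nrow(x$residues), stats::median(x$residues$kd[ok])))
  if (!is.null(x$kd_global)) {
    cat(sprintf("  global Kd = %.3g +/- %.2g\n", x$kd_global,
                x$kd_global_err))
  }
  invisible(x)
}

#' @export
coef.kd_fit <- function(object, ...) {
  stats::setNames(object$residues$kd, object$residues$residue)
}

#' @export
predict.kd_fit <- function(object, newdata, ...) {
  stopifnot(all(c("residue", "ligand") %in% names(newdata)))
  i <- match(newdata$residue, object$residues$residue)
  object$residues$ddmax[i] *
    binding_fraction(newdata$ligand, object$p_total, object$residues$kd[i])
}

#' Correlation between dispersion-derived and binding shift differences
#'
#' Pearson correlation (on magnitudes) between per-residue shift
#' differences from the exchange fit and from a ligand titration, plus the
#' least-squares slope through the origin.
#'
#' @param dw_disp,dw_bind named or parallel per-residue shift differences,
#'   ppm. If both carry names, they are matched by name.
#' @return list with `r`, `slope`, `n`.
#' @export
correlate_dw <- function(dw_disp, dw_bind) {
  if (!is.null(names(dw_disp)) && !is.null(names(dw_bind))) {
    shared <- intersect(names(dw_disp), names(dw_bind))
    dw_disp <- dw_disp[shared]; dw_bind <- dw_bind[shared]
  }
  ok <- is.finite(dw_disp) & is.finite(dw_bind)
  x <- abs(dw_disp[ok]); y <- abs(dw_bind[ok])
  if (length(x) < 3) stop("need at least 3 shared residues")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in the shift differences; correlation undefined")
  }
  list(r = stats::cor(x, y), slope = sum(x * y) / sum(x^2), n = length(x))
}
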