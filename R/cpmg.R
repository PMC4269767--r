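## CPMG relaxation dispersion: effective rates, the Carver-Richards closed
## form for two-state exchange, a Bloch-McConnell numerical oracle, flatness
## testing and the global two-field fit.

#' Effective transverse relaxation rate from peak intensities
#'
#' Converts CPMG peak intensities to effective relaxation rates via
#' `R2eff = -1/T_relax * log(I/I0)`, where `I0` is the intensity of a
#' reference experiment recorded without the relaxation period. Errors are
#' propagated from the intensity errors in quadrature:
#' `(1/T_relax) * sqrt((sI/I)^2 + (sI0/I0)^2)`.
#'
#' Non-positive intensities (vanished peaks) are dropped to `NA` with a
#' warning rather than producing infinite rates.
#'
#' @param intensity peak intensity (partial peak volume) at a given CPMG
#'   frequency; vectorised.
#' @param i0 reference intensity (no relaxation delay).
#' @param t_relax constant relaxation delay in seconds (30 ms in a typical
#'   acquisition).
#' @param intensity_err,i0_err optional intensity errors for propagation.
#' @return data.frame with columns `r2eff` and `r2eff_err` (s^-1).
#' @export
r2eff_from_intensities <- function(intensity, i0, t_relax,
                                   intensity_err = 0, i0_err = 0) {
  stopifnot(t_relax > 0, all(i0 > 0))
  m <- max(length(intensity), length(i0))
  intensity <- rep_len(intensity, m)
  i0 <- rep_len(i0, m)
  intensity_err <- rep_len(intensity_err, m)
  i0_err <- rep_len(i0_err, m)
  bad <- !(intensity > 0)
  if (any(bad)) {
    warning(sum(bad), " non-positive intensit",
            if (sum(bad) == 1) "y" else "ies",
            " dropped (peak vanished during the CPMG period)")
  }
  r2 <- err <- rep(NA_real_, m)
  g <- !bad
  r2[g] <- -log(intensity[g] / i0[g]) / t_relax
  err[g] <- sqrt((intensity_err[g] / intensity[g])^2 +
                   (i0_err[g] / i0[g])^2) / t_relax
  data.frame(r2eff = r2, r2eff_err = err)
}

#' Per-point R2eff errors from repeat experiments
#'
#' When no other error estimate exists, dispersion experiments acquired with
#' repeat points (e.g. at 67 and 600 Hz) provide one: for each residue and
#' field the error is taken as the mean over repeated frequencies of half
#' the absolute difference between the repeats, and applied to every point
#' of that curve.
#'
#' @param data dispersion data.frame with columns `residue`, `field`,
#'   `nu_cpmg`, `r2eff` (and optionally `r2eff_err`, which is overwritten
#'   where missing).
#' @param floor minimum error assigned when repeats happen to coincide.
#' @return the data.frame with a filled `r2eff_err` column.
#' @export
repeat_errors <- function(data, floor = 0.05) {
  stopifnot(all(c("residue", "field", "nu_cpmg", "r2eff") %in% names(data)))
  if (is.null(data$r2eff_err)) data$r2eff_err <- NA_real_
  key <- interaction(data$residue, data$field, drop = TRUE)
  for (g in levels(key)) {
    idx <- which(key == g)
    if (all(is.finite(data$r2eff_err[idx]))) next
    nu <- data$nu_cpmg[idx]
    dup <- unique(nu[duplicated(nu)])
    if (length(dup) == 0) {
      stop("no repeat points for curve ", g,
           " and no r2eff_err supplied; cannot estimate errors")
    }
    halfdiff <- vapply(dup, function(v) {
      y <- data$r2eff[idx][nu == v]
      mean(abs(diff(y))) / 2
    }, numeric(1))
    data$r2eff_err[idx] <- max(mean(halfdiff), floor)
  }
  data
}

#' Carver-Richards R2eff for two-state exchange under CPMG
#'
#' Closed-form effective transverse relaxation rate for a two-state exchange
#' process (major-state population `pa`, exchange rate `kex = kAB + kBA`,
#' shift separation `dw` in rad/s) with equal intrinsic rates in both states,
#' evaluated at CPMG pulsing frequency `nu_cpmg = 1/(2*tau_cp)` where
#' `tau_cp` is the delay between successive 180-degree pulses.
#'
#' Uses the cosh^-1 of `D+ cosh(eta+) - D- cos(eta-)` form with
#' `psi = kex^2 - dw^2` and `zeta = -2 dw kex (pa - pb)`; large `eta+`
#' values are evaluated in the log domain so the expression cannot overflow.
#'
#' @param pa major-state population, in (0, 1].
#' @param kex total exchange rate constant, s^-1.
#' @param dw chemical-shift difference between the states, rad/s (the sign
#'   is immaterial).
#' @param r2_0 intrinsic transverse relaxation rate of both states, s^-1.
#' @param nu_cpmg CPMG frequency, Hz. All arguments are recycled.
#' @return R2eff in s^-1.
#' @seealso [bloch_mcconnell_r2eff()] for the numerical propagation oracle.
#' @export
carver_richards_r2eff <- function(pa, kex, dw, r2_0, nu_cpmg) {
  stopifnot(all(pa > 0), all(pa <= 1), all(kex >= 0), all(nu_cpmg > 0))
  m <- max(length(pa), length(kex), length(dw), length(r2_0), length(nu_cpmg))
  pa <- rep_len(pa, m); kex <- rep_len(kex, m); dw <- abs(rep_len(dw, m))
  r2_0 <- rep_len(r2_0, m); nu <- rep_len(nu_cpmg, m)

  out <- r2_0
  act <- pa < 1 - 1e-12 & kex > 0 & dw > 1e-12
  if (!any(act)) return(out)
  pa <- pa[act]; kex <- kex[act]; dw <- dw[act]
  r20 <- r2_0[act]; nu <- nu[act]
  pb <- 1 - pa
  tcp <- 1 / (2 * nu)

  psi <- kex^2 - dw^2
  zeta <- -2 * dw * kex * (pa - pb)
  root <- sqrt(psi^2 + zeta^2)
  Dp <- 0.5 * (1 + (psi + 2 * dw^2) / root)
  Dm <- 0.5 * (-1 + (psi + 2 * dw^2) / root)
  etap <- tcp / sqrt(2) * sqrt(pmax(root + psi, 0))
  etam <- tcp / sqrt(2) * sqrt(pmax(root - psi, 0))

  ach <- numeric(length(etap))
  big <- etap > 30
  if (any(!big)) {
    x <- Dp[!big] * cosh(etap[!big]) - Dm[!big] * cos(etam[!big])
    ach[!big] <- acosh(pmax(x, 1))
  }
  if (any(big)) {
    # acosh(x) ~ log(2x) for large x; cosh(eta+) evaluated in the log domain
    lx <- etap[big] +
      log(pmax(Dp[big] / 2 * (1 + exp(-2 * etap[big])) -
                 Dm[big] * cos(etam[big]) * exp(-etap[big]), 1e-300))
    ach[big] <- lx + log(2)
  }
  out[act] <- r20 + 0.5 * (kex - ach / tcp)
  out
}

#' Luz-Meiboom fast-exchange limit of the CPMG dispersion
#'
#' Valid when `kex` greatly exceeds `dw`; used as an analytical cross-check
#' of the numerical propagation.
#'
#' @inheritParams carver_richards_r2eff
#' @return R2eff in s^-1.
#' @export
luz_meiboom_r2eff <- function(pa, kex, dw, r2_0, nu_cpmg) {
  pb <- 1 - pa
  phi <- pa * pb * dw^2
  r2_0 + phi / kex * (1 - (4 * nu_cpmg / kex) * tanh(kex / (4 * nu_cpmg)))
}

#' Bloch-McConnell numerical R2eff for a CPMG experiment
#'
#' Propagates the complex transverse magnetisation of both exchanging states
#' through alternating free-precession/exchange evolution and ideal
#' 180-degree pulses (complex conjugation) for the full relaxation period,
#' then converts the surviving major-state signal to an effective rate. This
#' is the numerical ground truth against which the Carver-Richards closed
#' form is validated, and the model used by the synthetic-data generator.
#'
#' The relaxation period must contain a whole, even number of echo units
#' (`T_relax = n * tau_cp` with `n` even), so the pulse train is symmetric.
#'
#' @inheritParams carver_richards_r2eff
#' @param t_relax constant relaxation delay, s.
#' @return R2eff in s^-1.
#' @export
bloch_mcconnell_r2eff <- function(pa, kex, dw, r2_0, nu_cpmg,
                                  t_relax = 0.030) {
  stopifnot(all(pa > 0), all(pa <= 1), all(kex >= 0), all(nu_cpmg > 0),
            t_relax > 0)
  m <- max(length(pa), length(kex), length(dw), length(r2_0), length(nu_cpmg))
  pa <- rep_len(pa, m); kex <- rep_len(kex, m); dw <- rep_len(dw, m)
  r2_0 <- rep_len(r2_0, m); nu <- rep_len(nu_cpmg, m)

  n_echo <- 2 * nu * t_relax  # number of 180-degree pulses in t_relax
  if (any(abs(n_echo - round(n_echo)) > 1e-6) ||
      any(round(n_echo) < 2) || any(round(n_echo) %% 2 != 0)) {
    stop("t_relax must contain an even integer number of echo units ",
         "(t_relax = n/(2*nu_cpmg), n even) at every nu_cpmg")
  }
  n_echo <- round(n_echo)

  out <- r2_0
  act <- pa < 1 - 1e-12 & kex > 0 & abs(dw) > 1e-12
  if (!any(act)) return(out)

  i <- which(act)
  pa_ <- pa[i]; pb_ <- 1 - pa_; kex_ <- kex[i]; dw_ <- dw[i]
  nu_ <- nu[i]; ne <- n_echo[i]
  tau <- 1 / (4 * nu_)  # half the inter-pulse delay

  ## free evolution generator with the intrinsic rate factored out:
  ## L0 = [[-kAB, kBA], [kAB, -kBA + i*dw]]
  kab <- pb_ * kex_; kba <- pa_ * kex_
  a <- complex(real = -kab)
  b <- complex(real = kba)
  cc <- complex(real = kab)
  d <- complex(real = -kba, imaginary = dw_)

  s <- (a + d) / 2
  q <- sqrt(((a - d) / 2)^2 + b * cc)
  tiny <- Mod(q) < 1e-9 * (Mod(s) + 1)
  if (any(tiny)) q[tiny] <- q[tiny] + 1e-9 * (Mod(s[tiny]) + 1)
  l1 <- s + q; l2 <- s - q
  e1 <- exp(l1 * tau); e2 <- exp(l2 * tau)
  dl <- l2 - l1

  U11 <- (e1 * (l2 - a) - e2 * (l1 - a)) / dl
  U12 <- b * (e2 - e1) / dl
  U21 <- (l1 - a) * (l2 - a) * (e1 - e2) / (b * dl)
  U22 <- ((l2 - a) * e2 - (l1 - a) * e1) / dl

  ## two-echo propagator P = U Conj(U) Conj(U) U (180 pulses = conjugation)
  C11 <- Conj(U11); C12 <- Conj(U12); C21 <- Conj(U21); C22 <- Conj(U22)
  B11 <- C11 * C11 + C12 * C21; B12 <- C11 * C12 + C12 * C22
  B21 <- C21 * C11 + C22 * C21; B22 <- C21 * C12 + C22 * C22
  T11 <- U11 * B11 + U12 * B21; T12 <- U11 * B12 + U12 * B22
  T21 <- U21 * B11 + U22 * B21; T22 <- U21 * B12 + U22 * B22
  P11 <- T11 * U11 + T12 * U21; P12 <- T11 * U12 + T12 * U22
  P21 <- T21 * U11 + T22 * U21; P22 <- T21 * U12 + T22 * U22

  ## eigen-power of P applied to M0 = (pa, pb)
  mm <- ne / 2
  sp <- (P11 + P22) / 2
  qp <- sqrt(((P11 - P22) / 2)^2 + P12 * P21)
  mu1 <- sp + qp; mu2 <- sp - qp
  det <- P12 * (mu2 - mu1)
  ok <- Mod(det) > 1e-280 & Mod(qp) > 1e-12 * (Mod(sp) + 1e-12)

  MA <- complex(length.out = length(i))
  if (any(ok)) {
    alpha <- (pa_[ok] * (mu2[ok] - P11[ok]) - P12[ok] * pb_[ok]) / det[ok]
    beta <- (-pa_[ok] * (mu1[ok] - P11[ok]) + P12[ok] * pb_[ok]) / det[ok]
    MA[ok] <- P12[ok] * (alpha * mu1[ok]^mm[ok] + beta * mu2[ok]^mm[ok])
  }
  if (any(!ok)) {
    ## rare degenerate lanes: iterate the echoes explicitly
    for (j in which(!ok)) {
      U <- matrix(c(U11[j], U21[j], U12[j], U22[j]), 2, 2)
      M <- complex(real = c(pa_[j], pb_[j]))
      for (k in seq_len(ne[j])) M <- U %*% Conj(U %*% M)
      MA[j] <- M[1]
    }
  }
  out[i] <- r2_0[i] - log(pmax(Mod(MA) / pa_, 1e-300)) / t_relax
  out
}

#' Flatness test for a single dispersion curve
#'
#' Compares a constant model against an exchange model (the fast-limit
#' dispersion form with parameters `r2_0`, `phi = pa*pb*dw^2` and `kex`) by
#' an F-test. A curve is called flat when the exchange model does not
#' improve the fit significantly at level `alpha`.
#'
#' @param nu_cpmg CPMG frequencies, Hz (>= 4 points).
#' @param r2eff effective rates, s^-1.
#' @param r2eff_err optional per-point errors used as weights.
#' @param alpha significance level of the F-test (default 0.01).
#' @return list with elements `flat` (logical), `p_value`, `statistic`
#'   (the F statistic; 0 for a perfectly constant curve), `ss_flat`,
#'   `ss_exchange`, `amplitude` (fitted exchange amplitude at nu -> 0).
#' @export
detect_flat <- function(nu_cpmg, r2eff, r2eff_err = NULL, alpha = 0.01) {
  keep <- is.finite(nu_cpmg) & is.finite(r2eff)
  nu_cpmg <- nu_cpmg[keep]; r2eff <- r2eff[keep]
  if (!is.null(r2eff_err)) r2eff_err <- rep_len(r2eff_err, length(keep))[keep]
  n <- length(r2eff)
  if (n < 4) stop("at least 4 dispersion points are required")
  w <- if (is.null(r2eff_err) || !all(is.finite(r2eff_err)) ||
           any(r2eff_err <= 0)) rep(1, n) else 1 / r2eff_err^2

  mu <- sum(w * r2eff) / sum(w)
  ss0 <- sum(w * (r2eff - mu)^2)

  ## exchange alternative: r2_0 profiled analytically, grid+polish on
  ## (phi, kex) of the fast-limit form
  shape <- function(kex) 1 - (4 * nu_cpmg / kex) * tanh(kex / (4 * nu_cpmg))
  ss_exch <- function(par) {   # par = (log phi, log kex)
    f <- exp(par[1]) / exp(par[2]) * shape(exp(par[2]))
    r20 <- sum(w * (r2eff - f)) / sum(w)
    sum(w * (r20 + f - r2eff)^2)
  }
  amp0 <- max(r2eff) - min(r2eff)
  amp0 <- max(amp0, 1e-8)
  best <- NULL
  for (kex0 in c(100, 300, 1000, 3000)) {
    p0 <- c(log(amp0 * kex0), log(kex0))
    o <- stats::optim(p0, ss_exch, method = "Nelder-Mead",
                      control = list(maxit = 300, reltol = 1e-10))
    if (is.null(best) || o$value < best$value) best <- o
  }
  ss1 <- min(best$value, ss0)
  df2 <- n - 3
  stat <- if (ss1 <= 0) Inf else ((ss0 - ss1) / 2) / (ss1 / df2)
  if (ss0 <= 1e-300) stat <- 0   # perfectly constant curve
  p <- stats::pf(stat, 2, df2, lower.tail = FALSE)
  list(flat = p >= alpha, p_value = p, statistic = stat,
       ss_flat = ss0, ss_exchange = ss1,
       amplitude = exp(best$par[1]) / exp(best$par[2]))
}

## --- global two-field Carver-Richards fit -------------------------------

## parameter transforms: pa in (0.5, 1), kex > 0, dw > 0
.pa_to_par <- function(pa) stats::qlogis((pa - 0.5) / 0.5)
.par_to_pa <- function(p) 0.5 + 0.5 * stats::plogis(p)

#' Global two-state exchange fit of CPMG dispersion data
#'
#' Fits the Carver-Richards closed form to dispersion curves of several
#' residues, possibly at several static fields, with a single shared
#' exchange process: one global (pA, kex), one shift difference per residue
#' shared across fields in ppm (converted to rad/s with each field's 15N
#' frequency), and one intrinsic rate R2,0 per residue per field. R2,0 is
#' profiled analytically (it enters the model additively), so the nonlinear
#' search runs over pA, kex and the per-residue shift differences only,
#' with multi-start initialisation over a log-spaced kex grid and a pA grid.
#' Parameter uncertainties come from Monte-Carlo resampling of the data
#' from their errors.
#'
#' @param data data.frame with columns `residue`, `field` (1H MHz),
#'   `nu_cpmg` (Hz), `r2eff` (s^-1) and optionally `r2eff_err` (s^-1).
#' @param residues optional subset of residues to fit (e.g. the non-flat
#'   curves); default all.
#' @param model forward model: `"cr"` (default) fits the Carver-Richards
#'   closed form; `"bm"` fits the exact Bloch-McConnell propagation for the
#'   finite relaxation period. The closed form is the asymptotic
#'   (many-echo) eigenvalue rate and deviates from the finite-period
#'   propagation at the slowest pulsing rates when exchange is slow; use
#'   `"bm"` when the data were generated (or are believed to behave) as a
#'   finite echo train, e.g. for round-trip validation against
#'   [gen_cpmg_dataset()].
#' @param t_relax relaxation period (s) for `model = "bm"`; defaults to the
#'   `t_relax` attribute of `data`, else 0.030.
#' @param n_mc number of Monte-Carlo resampling draws for parameter errors
#'   (0 disables).
#' @param seed seed for the Monte-Carlo resampling.
#' @param kex_starts,pa_starts multi-start initialisation grids.
#' @param dw_max upper bound (ppm) for shift-difference initialisation.
#' @return an object of class `"exchange_fit"` with components `pa`, `kex`
#'   (s^-1), `tau_ex_ms` (= 1000/kex), `residues` (per-residue shift
#'   differences in ppm with Monte-Carlo errors and 95% intervals), `r2_0`
#'   (per residue and field), `chi2`, `chi2_red`, `global` (summary row
#'   with errors), `mc` (draws), and the fitted data. Supports `print()`,
#'   `summary()`, `coef()`, `predict()` and `plot()`.
#' @export
fit_dispersion <- function(data, residues = NULL, model = c("cr", "bm"),
                           t_relax = NULL, n_mc = 100, seed = NULL,
                           kex_starts = exp(seq(log(50), log(5000),
                                                length.out = 8)),
                           pa_starts = c(0.9, 0.95, 0.99),
                           dw_max = 8) {
  stopifnot(all(c("residue", "field", "nu_cpmg", "r2eff") %in% names(data)))
  model <- match.arg(model)
  if (is.null(t_relax)) t_relax <- attr(data, "t_relax") %||% 0.030
  fwd <- if (model == "cr") {
    function(pa, kex, dw_rad, nu) carver_richards_r2eff(pa, kex, dw_rad, 0, nu)
  } else {
    function(pa, kex, dw_rad, nu) {
      bloch_mcconnell_r2eff(pa, kex, dw_rad, 0, nu, t_relax)
    }
  }
  if (!is.null(residues)) data <- data[data$residue %in% residues, ]
  data <- data[is.finite(data$r2eff) & is.finite(data$nu_cpmg), ]
  res_lev <- sort(unique(data$residue))
  fld_lev <- sort(unique(data$field))
  R <- length(res_lev); FF <- length(fld_lev)
  if (R < 2) stop("at least 2 residues are required for a global fit")
  ri <- match(data$residue, res_lev)
  gi <- as.integer(interaction(ri, match(data$field, fld_lev), drop = FALSE))
  obs <- data$r2eff
  nu <- data$nu_cpmg
  fmhz <- data$field
  err <- data$r2eff_err
  if (is.null(err) || !all(is.finite(err)) || any(err <= 0)) err <- rep(1, length(obs))
  w <- 1 / err^2
  sw <- sqrt(w)
  swg <- tapply(w, gi, sum)

  n_obs <- length(obs)
  n_par <- 2 + R + R * FF

  resid_fun <- function(par) {
    pa <- .par_to_pa(par[1])
    kex <- exp(par[2])
    dw_ppm <- exp(par[3:(2 + R)])
    rex <- fwd(pa, kex, ppm_to_rads(dw_ppm[ri], fmhz), nu)
    d <- obs - rex
    r20 <- tapply(w * d, gi, sum) / swg
    (rex + r20[gi] - obs) * sw
  }

  ## residue-wise initial dw from the fast-limit amplitude relation
  amp <- tapply(obs, ri, function(y) max(y) - min(y))
  run_start <- function(pa0, kex0, maxiter = 100) {
    dw0 <- sqrt(pmax(amp, 0.2) * kex0 / (pa0 * (1 - pa0)))  # rad/s
    dw0_ppm <- pmin(pmax(rads_to_ppm(dw0, mean(fld_lev)), 0.05), dw_max)
    p0 <- unname(c(.pa_to_par(pa0), log(kex0), log(dw0_ppm)))
    minpack.lm::nls.lm(p0, fn = resid_fun,
                       control = minpack.lm::nls.lm.control(
                         maxiter = maxiter, ptol = 1e-12, ftol = 1e-12))
  }
  best <- NULL
  for (kex0 in kex_starts) for (pa0 in pa_starts) {
    fit <- tryCatch(run_start(pa0, kex0), error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("global dispersion fit failed to converge")

  unpack <- function(par) {
    par <- unname(par)
    pa <- .par_to_pa(par[1]); kex <- exp(par[2])
    dw_ppm <- exp(par[3:(2 + R)])
    rex <- fwd(pa, kex, ppm_to_rads(dw_ppm[ri], fmhz), nu)
    r20 <- as.numeric(tapply(w * (obs - rex), gi, sum) / swg)
    list(pa = pa, kex = kex, dw_ppm = dw_ppm, r2_0 = r20,
         fitted = rex + r20[gi])
  }
  est <- unpack(best$par)
  chi2 <- sum(w * (est$fitted - obs)^2)
  chi2_red <- chi2 / max(n_obs - n_par, 1)

  degenerate <- est$pa < 0.55 && all(est$dw_ppm < 0.05)
  if (degenerate) {
    warning("degenerate exchange fit: pA near 0.5 with tiny shift ",
            "differences; parameters are unlikely to be meaningful")
  }

  ## Monte-Carlo resampling of the data from their errors
  mc <- NULL
  if (n_mc > 0) {
    draws <- .with_seed(seed, {
      t(vapply(seq_len(n_mc), function(k) {
        obs_k <- est$fitted + stats::rnorm(n_obs, 0, err)
        rf <- function(par) {
          pa <- .par_to_pa(par[1]); kex <- exp(par[2])
          dw_ppm <- exp(par[3:(2 + R)])
          rex <- fwd(pa, kex, ppm_to_rads(dw_ppm[ri], fmhz), nu)
          d <- obs_k - rex
          r20 <- tapply(w * d, gi, sum) / swg
          (rex + r20[gi] - obs_k) * sw
        }
        f <- minpack.lm::nls.lm(best$par, fn = rf,
                                control = minpack.lm::nls.lm.control(
                                  maxiter = 50, ptol = 1e-10, ftol = 1e-10))
        c(.par_to_pa(f$par[1]), exp(f$par[2]), exp(f$par[3:(2 + R)]))
      }, numeric(2 + R)))
    })
    colnames(draws) <- c("pa", "kex", paste0("dw_", res_lev))
    mc <- as.data.frame(draws)
  }

  qlo <- function(x) unname(stats::quantile(x, 0.025))
  qhi <- function(x) unname(stats::quantile(x, 0.975))
  res_tab <- data.frame(residue = res_lev, dw_ppm = est$dw_ppm)
  if (!is.null(mc)) {
    dwm <- as.matrix(mc[, -(1:2), drop = FALSE])
    res_tab$dw_err <- apply(dwm, 2, stats::sd)
    res_tab$dw_lo <- apply(dwm, 2, qlo)
    res_tab$dw_hi <- apply(dwm, 2, qhi)
  }
  r20_tab <- data.frame(residue = res_lev[rep(seq_len(R), FF)],
                        field = rep(fld_lev, each = R),
                        r2_0 = est$r2_0)
  glob <- data.frame(
    pa = est$pa, kex = est$kex, tau_ex_ms = 1000 / est$kex,
    pa_err = if (!is.null(mc)) stats::sd(mc$pa) else NA_real_,
    kex_err = if (!is.null(mc)) stats::sd(mc$kex) else NA_real_,
    tau_ex_err_ms = if (!is.null(mc)) stats::sd(1000 / mc$kex) else NA_real_,
    pa_lo = if (!is.null(mc)) qlo(mc$pa) else NA_real_,
    pa_hi = if (!is.null(mc)) qhi(mc$pa) else NA_real_,
    kex_lo = if (!is.null(mc)) qlo(mc$kex) else NA_real_,
    kex_hi = if (!is.null(mc)) qhi(mc$kex) else NA_real_,
    chi2_red = chi2_red)

  out <- list(pa = est$pa, kex = est$kex, tau_ex_ms = 1000 / est$kex,
              residues = res_tab, r2_0 = r20_tab, global = glob,
              chi2 = chi2, chi2_red = chi2_red,
              n_obs = n_obs, n_par = n_par, degenerate = degenerate,
              mc = mc, data = transform(data, fitted = est$fitted),
              fields = fld_lev, model = model, t_relax = t_relax,
              call = match.call())
  class(out) <- "exchange_fit"
  out
}

#' @export
print.exchange_fit <- function(x, ...) {
  cat("Global two-state exchange fit (",
      if (identical(x$model, "bm")) "Bloch-McConnell propagation"
      else "Carver-Richards", ")\n", sep = "")
  cat(sprintf("  pA     = %.4f", x$pa))
  if (is.finite(x$global$pa_err)) cat(sprintf(" +/- %.4f", x$global$pa_err))
  cat("\n")
  cat(sprintf("  kex    = %.1f s^-1", x$kex))
  if (is.finite(x$global$kex_err)) cat(sprintf(" +/- %.1f", x$global$kex_err))
  cat("\n")
  cat(sprintf("  tau_ex = %.2f ms", x$tau_ex_ms))
  if (is.finite(x$global$tau_ex_err_ms))
    cat(sprintf(" +/- %.2f", x$global$tau_ex_err_ms))
  cat("\n")
  cat(sprintf("  %d residues, %d fields (%s MHz), reduced chi2 = %.3f\n",
              nrow(x$residues), length(x$fields),
              paste(x$fields, collapse = "/"), x$chi2_red))
  invisible(x)
}

#' @export
summary.exchange_fit <- function(object, ...) {
  print(object)
  cat("\nPer-residue |dw| (ppm):\n")
  print(object$residues, row.names = FALSE, digits = 4)
  invisible(object)
}

#' @export
coef.exchange_fit <- function(object, ...) {
  c(pa = object$pa, kex = object$kex,
    stats::setNames(object$residues$dw_ppm,
                    paste0("dw_", object$residues$residue)))
}

#' @export
predict.exchange_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$data$fitted)
  stopifnot(all(c("residue", "field", "nu_cpmg") %in% names(newdata)))
  dw <- object$residues$dw_ppm[match(newdata$residue,
                                     object$residues$residue)]
  key_new <- paste(newdata$residue, newdata$field)
  key_r20 <- paste(object$r2_0$residue, object$r2_0$field)
  r20 <- object$r2_0$r2_0[match(key_new, key_r20)]
  if (identical(object$model, "bm")) {
    bloch_mcconnell_r2eff(object$pa, object$kex,
                          ppm_to_rads(dw, newdata$field), r20,
                          newdata$nu_cpmg, object$t_relax)
  } else {
    carver_richards_r2eff(object$pa, object$kex,
                          ppm_to_rads(dw, newdata$field), r20,
                          newdata$nu_cpmg)
  }
}

#' @export
plot.exchange_fit <- function(x, residues = NULL, ...) {
  d <- x$data
  if (is.null(residues)) residues <- unique(d$residue)
  op <- graphics::par(mfrow = grDevices::n2mfrow(length(residues)),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (r in residues) {
    di <- d[d$residue == r, ]
    graphics::plot(di$nu_cpmg, di$r2eff, pch = 19,
                   col = as.integer(factor(di$field)),
                   xlab = expression(nu[CPMG] ~ "(Hz)"),
                   ylab = expression(R[2][",eff"] ~ (s^-1)),
                   main = paste("residue", r), ...)
    for (f in unique(di$field)) {
      nn <- seq(min(di$nu_cpmg), max(di$nu_cpmg), length.out = 100)
      pred <- predict(x, data.frame(residue = r, field = f, nu_cpmg = nn))
      graphics::lines(nn, pred, col = as.integer(factor(f, unique(di$field))))
    }
  }
  invisible(x)
}
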