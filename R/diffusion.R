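## Pulsed-field-gradient stimulated-echo diffusion analysis. The
## stimulated-echo timing factors (gamma^2 delta^2 (Delta - delta/3) and
## friends) are folded into the per-sample attenuation constant: they cancel
## against an internal reference measured under identical conditions, which
## is how hydrodynamic radii are obtained without absolute calibration.

#' Fit a diffusion attenuation decay
#'
#' Least squares of `I(G) = I0 * exp(-d * G^2)` over the gradient series;
#' `d` absorbs the gradient timing constants. The RMSD is kept for ranking
#' residues in [aggregate_best()].
#'
#' @param gradients gradient strengths, G/cm (>= 4 values), or `NULL` if
#'   `data` is given.
#' @param intensity observed intensities.
#' @param err optional intensity errors (weights).
#' @param data alternatively a decay data.frame whose `x` column is the
#'   squared gradient, as produced by [gen_diffusion_decays()].
#' @return object of class `"decay_fit"` (see [fit_exponential()]) whose
#'   `rate` is the attenuation constant `d` per (G/cm)^2; `d = 0` within
#'   error is flagged as non-diffusing via a warning.
#' @export
fit_attenuation <- function(gradients = NULL, intensity = NULL, err = NULL,
                            data = NULL) {
  if (is.null(data)) {
    stopifnot(!is.null(gradients), all(gradients > 0))
    if (length(gradients) < 4) stop("need at least 4 gradient strengths")
    data <- data.frame(x = gradients^2, intensity = intensity)
    if (!is.null(err)) data$err <- err
  } else if (length(unique(data$x)) < 4) {
    stop("need at least 4 gradient strengths")
  }
  fit <- fit_exponential(data = data)
  if (is.finite(fit$rate_err) && abs(fit$rate) <= 2 * fit$rate_err ||
      fit$rate <= 0) {
    warning("attenuation rate is zero within error: non-diffusing signal?")
  }
  fit
}

#' Aggregate the best-fit diffusion attenuation rates
#'
#' Selects the `n` residues with the smallest fit RMSD (ties broken by
#' ascending residue number, for determinism) and returns the mean and SD
#' of their attenuation rates.
#'
#' @param fits data.frame with columns `residue`, `d`, `rmsd`, or a named
#'   list of `decay_fit` objects (names = residues).
#' @param n number of best-fit residues to average (default 20).
#' @return list with `mean_d`, `sd_d` and the selected `residues`.
#' @export
aggregate_best <- function(fits, n = 20) {
  if (!is.data.frame(fits)) {
    fits <- data.frame(
      residue = as.numeric(names(fits)),
      d = vapply(fits, function(f) f$rate, numeric(1)),
      rmsd = vapply(fits, function(f) f$rmsd, numeric(1)))
  }
  stopifnot(all(c("residue", "d", "rmsd") %in% names(fits)))
  if (nrow(fits) < n) {
    stop("fewer residues (", nrow(fits), ") than requested n = ", n)
  }
  sel <- fits[order(fits$rmsd, fits$residue), ][seq_len(n), ]
  list(mean_d = mean(sel$d), sd_d = stats::sd(sel$d),
       residues = sel$residue)
}

#' Hydrodynamic radius from an internal reference
#'
#' At equal temperature, viscosity and gradient calibration, diffusion
#' coefficients are inversely proportional to hydrodynamic radii, so
#' `r_h = r_reference * d_reference / d_protein`. The default reference
#' radius is 2.12 Angstrom (dioxane).
#'
#' @param d_protein,d_reference attenuation rates of protein and reference
#'   from the same sample series.
#' @param r_reference reference hydrodynamic radius, Angstrom.
#' @return hydrodynamic radius in Angstrom.
#' @export
hydrodynamic_radius <- function(d_protein, d_reference, r_reference = 2.12) {
  if (any(d_protein <= 0) || any(d_reference <= 0)) {
    stop("attenuation rates must be positive")
  }
  r_reference * d_reference / d_protein
}

#' Stokes-Einstein translational diffusion
#'
#' `Dt = kB * T / (6 * pi * eta * r_h)` for a sphere of hydrodynamic
#' radius `r_h`; [rh_from_dt()] solves the same relation for the radius.
#'
#' @param r_h hydrodynamic radius, Angstrom.
#' @param temperature temperature, K (default 298).
#' @param viscosity solvent viscosity, Pa s (default water at 298 K,
#'   0.891e-3).
#' @return translational diffusion coefficient in m^2/s.
#' @export
stokes_einstein <- function(r_h, temperature = 298, viscosity = 0.891e-3) {
  stopifnot(all(r_h > 0), temperature > 0, viscosity > 0)
  .nmr$kB * temperature / (6 * pi * viscosity * r_h * 1e-10)
}

#' @rdname stokes_einstein
#' @param dt translational diffusion coefficient, m^2/s.
#' @export
rh_from_dt <- function(dt, temperature = 298, viscosity = 0.891e-3) {
  stopifnot(all(dt > 0), temperature > 0, viscosity > 0)
  .nmr$kB * temperature / (6 * pi * viscosity * dt) * 1e10
}

#' Relative diffusion between two samples
#'
#' Ratio of aggregate attenuation means (e.g. ligand-bound over apo), with
#' the error from the aggregate SDs by quadrature. Gradient timing factors
#' cancel in the ratio.
#'
#' @param agg_a,agg_b aggregates from [aggregate_best()]; the ratio is
#'   `b / a` (so `a` = apo gives Dt_bound/Dt_apo).
#' @return list with `ratio` and `ratio_err`.
#' @export
relative_diffusion <- function(agg_a, agg_b) {
  ratio <- agg_b$mean_d / agg_a$mean_d
  ratio_err <- ratio * sqrt((agg_a$sd_d / agg_a$mean_d)^2 +
                              (agg_b$sd_d / agg_b$mean_d)^2)
  list(ratio = ratio, ratio_err = ratio_err)
}
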