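## Synthetic-data generators. Every observable the pipeline consumes can be
## generated with known ground truth, a stated noise model (independent
## Gaussian per point) and an explicit seed, so all downstream stages are
## testable without spectrometer data. Default grids and delays copy the
## acquisition values of the study the package emulates (two fields, 500 and
## 800 MHz; CPMG frequencies 33-933 Hz with repeats at 67 and 600 Hz and a
## 30 ms relaxation period; R1 delays 10.9-870.4 ms; R1rho delays
## 10-100 ms; gradients 22-58 G/cm), so synthetic experiments are shaped
## like the real ones.

#' Ground-truth parameter set for the synthetic study
#'
#' Collects the true parameters from which every synthetic observable is
#' generated: a two-state exchange process, per-residue model-free
#' parameters, translational diffusion attenuation constants, and a 1:1
#' binding titration. Defaults describe a well-folded ~17 kDa protein with
#' a single millisecond exchange process (`tau_ex = 1/kex = 3.5 ms`),
#' backbone shift separations below 1 ppm, an isotropic rotational
#' correlation time of 8.7 ns, and a micromolar-affinity ligand site.
#'
#' @param residues residue numbers carrying the synthetic observables.
#' @param pa major-state population of the exchange process.
#' @param kex exchange rate constant, s^-1.
#' @param dw_ppm per-residue 15N shift difference between the exchanging
#'   states, ppm (recycled over `residues`).
#' @param r2_0 named vector of intrinsic transverse rates (s^-1), one per
#'   static field (names are 1H frequencies in MHz).
#' @param tau_c_ns isotropic rotational correlation time, ns.
#' @param s2 per-residue Lipari-Szabo order parameter (recycled).
#' @param tau_e_ps per-residue internal correlation time, ps (recycled).
#' @param r1 per-residue longitudinal rate used only when decays are
#'   generated directly, s^-1.
#' @param d_protein,d_reference diffusion attenuation constants of the
#'   protein and the internal small-molecule reference, per (G/cm)^2. The
#'   default ratio reproduces a 20.1 A protein measured against a 2.12 A
#'   dioxane reference.
#' @param kd dissociation constant of the titration, in the same
#'   concentration unit as `p_total` (defaults are molar: 7 uM).
#' @param p_total total protein concentration in the titration (0.2 mM).
#' @param ddmax_ppm per-residue CSP at saturation, ppm (recycled).
#' @return a list of class `"ground_truth"`.
#' @export
ground_truth <- function(residues = 1:8,
                         pa = 0.95,
                         kex = 1000 / 3.5,
                         dw_ppm = seq(0.3, 1.0, length.out = length(residues)),
                         r2_0 = c("500" = 13, "800" = 16),
                         tau_c_ns = 8.7,
                         s2 = 0.85,
                         tau_e_ps = 50,
                         r1 = 1.4,
                         d_protein = 6e-4,
                         d_reference = 6e-4 * (20.1 / 2.12),
                         kd = 7e-6,
                         p_total = 2e-4,
                         ddmax_ppm = 0.15) {
  n <- length(residues)
  stopifnot(pa > 0, pa <= 1, kex >= 0, all(r2_0 >= 0), kd > 0, p_total > 0,
            tau_c_ns > 0, all(tau_e_ps >= 0), d_protein > 0, d_reference > 0)
  s2 <- rep_len(s2, n)
  if (any(s2 < 0 | s2 > 1)) stop("S2 must lie in [0, 1]")
  truth <- list(residues = residues,
                exchange = list(pa = pa, kex = kex,
                                dw_ppm = rep_len(abs(dw_ppm), n),
                                r2_0 = r2_0),
                modelfree = list(tau_c_ns = tau_c_ns, s2 = s2,
                                 tau_e_ps = rep_len(tau_e_ps, n)),
                relaxation = list(r1 = rep_len(r1, n)),
                diffusion = list(d_protein = d_protein,
                                 d_reference = d_reference),
                titration = list(kd = kd, p_total = p_total,
                                 ddmax_ppm = rep_len(ddmax_ppm, n)))
  class(truth) <- "ground_truth"
  truth
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Synthetic ground truth:", length(x$residues), "residues\n")
  cat(sprintf("  exchange : pA = %.3f, kex = %.1f s^-1 (tau_ex = %.2f ms), |dw| %.2f-%.2f ppm\n",
              x$exchange$pa, x$exchange$kex, 1000 / x$exchange$kex,
              min(x$exchange$dw_ppm), max(x$exchange$dw_ppm)))
  cat(sprintf("  modelfree: tau_c = %.2f ns, S2 %.2f-%.2f, tau_e %.0f ps\n",
              x$modelfree$tau_c_ns, min(x$modelfree$s2), max(x$modelfree$s2),
              max(x$modelfree$tau_e_ps)))
  cat(sprintf("  diffusion: d_ref/d_prot = %.3f\n",
              x$diffusion$d_reference / x$diffusion$d_protein))
  cat(sprintf("  titration: Kd = %.3g, P_total = %.3g, ddmax <= %.2f ppm\n",
              x$titration$kd, x$titration$p_total,
              max(x$titration$ddmax_ppm)))
  invisible(x)
}

#' Default CPMG frequency grid
#'
#' CPMG frequencies commensurate with a 30 ms relaxation period, spanning
#' 33-933 Hz with repeat points at 67 and 600 Hz.
#'
#' @param t_relax relaxation period, s.
#' @return vector of CPMG frequencies in Hz.
#' @export
default_nu_cpmg <- function(t_relax = 0.030) {
  n <- c(2, 4, 4, 8, 12, 16, 20, 24, 28, 32, 36, 36, 40, 44, 48, 52, 56)
  n / (2 * t_relax)
}

#' Default relaxation delay sets
#'
#' `r1_delays()` spans 10.9-870.4 ms; `r1rho_delays()` spans 10-100 ms.
#' @return delay vector in seconds.
#' @export
r1_delays <- function() {
  c(10.9, 54.4, 108.8, 217.6, 326.4, 435.2, 544.0, 652.8, 761.6, 870.4) / 1000
}

#' @rdname r1_delays
#' @export
r1rho_delays <- function() {
  c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100) / 1000
}

#' Default pulsed-field-gradient strengths (22-58 G/cm)
#' @return gradient strengths in G/cm.
#' @export
default_gradients <- function() seq(22, 58, by = 4)

#' Simulate a CPMG relaxation dispersion dataset
#'
#' Noiseless curves are exactly the Bloch-McConnell propagation
#' ([bloch_mcconnell_r2eff()]) evaluated at the ground-truth parameters;
#' Gaussian noise of standard deviation `noise_sd` (s^-1) is added
#' independently per point.
#'
#' @param truth a [ground_truth()] object.
#' @param fields static fields as 1H Larmor frequencies, MHz.
#' @param nu_grid CPMG frequencies, Hz.
#' @param t_relax relaxation period, s.
#' @param noise_sd Gaussian noise SD on R2eff, s^-1 (>= 0).
#' @param seed RNG seed; the same seed reproduces the dataset exactly.
#' @return data.frame (`residue`, `field`, `nu_cpmg`, `r2eff`,
#'   `r2eff_err`) with attribute `t_relax`.
#' @export
gen_cpmg_dataset <- function(truth, fields = c(500, 800),
                             nu_grid = default_nu_cpmg(t_relax),
                             t_relax = 0.030, noise_sd = 0.3, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"), length(nu_grid) > 0,
            all(nu_grid > 0))
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  ex <- truth$exchange
  r2_0 <- ex$r2_0[as.character(fields)]
  if (any(is.na(r2_0))) stop("truth$exchange$r2_0 lacks a value for some field")
  grid <- expand.grid(nu_cpmg = nu_grid, residue = truth$residues,
                      field = fields, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("residue", "field", "nu_cpmg")]
  dw <- ex$dw_ppm[match(grid$residue, truth$residues)]
  grid$r2eff <- bloch_mcconnell_r2eff(ex$pa, ex$kex,
                                      ppm_to_rads(dw, grid$field),
                                      r2_0[as.character(grid$field)],
                                      grid$nu_cpmg, t_relax)
  if (noise_sd > 0) {
    grid$r2eff <- grid$r2eff +
      .with_seed(seed, stats::rnorm(nrow(grid), 0, noise_sd))
  }
  grid$r2eff_err <- rep(noise_sd, nrow(grid))
  rownames(grid) <- NULL
  attr(grid, "t_relax") <- t_relax
  grid
}

#' Simulate a mono-exponential relaxation decay
#'
#' Expected intensity at delay `t` is `I0 * exp(-rate * t)`; Gaussian noise
#' with standard deviation `noise_frac * I0` is added per point.
#'
#' @param rate decay rate, s^-1 (non-negative).
#' @param i0 intensity at zero delay.
#' @param delays delay values, s (or squared gradients for diffusion use).
#' @param noise_frac noise SD as a fraction of `i0`.
#' @param seed RNG seed.
#' @return data.frame (`x`, `intensity`, `err`) with `x_kind = "time_s"`.
#' @export
gen_relaxation_decays <- function(rate, i0 = 100, delays = r1_delays(),
                                  noise_frac = 0, seed = NULL) {
  if (length(delays) == 0 || any(delays < 0)) {
    stop("delays must be non-empty and non-negative")
  }
  if (rate < 0) stop("rate must be non-negative")
  y <- i0 * exp(-rate * delays)
  if (noise_frac > 0) {
    y <- y + .with_seed(seed, stats::rnorm(length(delays), 0, noise_frac * i0))
  }
  out <- data.frame(x = delays, intensity = y,
                    err = rep(noise_frac * i0, length(delays)))
  attr(out, "x_kind") <- "time_s"
  out
}

#' Simulate pulsed-field-gradient diffusion decays
#'
#' Protein and reference intensities decay as `I0 * exp(-d * G^2)` with the
#' respective attenuation constants; the stimulated-echo timing factors are
#' folded into `d` (they cancel against the internal reference).
#'
#' @param truth a [ground_truth()] object (uses `d_protein`,
#'   `d_reference`), or `NULL` if `d_atten` is given.
#' @param gradients gradient strengths, G/cm (positive).
#' @param d_atten optional explicit attenuation constant per (G/cm)^2
#'   (overrides `truth`; generates a single series).
#' @param i0 zero-gradient intensity.
#' @param noise_frac Gaussian noise SD as a fraction of `i0`.
#' @param reference_noise_frac fractional noise of the reference series.
#'   The small-molecule reference resonance is far more intense than any
#'   single amide peak, so its fractional noise is much lower; the default
#'   is `noise_frac / 20`.
#' @param seed RNG seed.
#' @return if `d_atten` is given, a single decay data.frame (`x` is the
#'   squared gradient, (G/cm)^2); otherwise a list with `protein` (one
#'   series per residue in `truth`) and `reference`.
#' @export
gen_diffusion_decays <- function(truth = NULL, gradients = default_gradients(),
                                 d_atten = NULL, i0 = 100, noise_frac = 0,
                                 reference_noise_frac = noise_frac / 20,
                                 seed = NULL) {
  if (any(gradients <= 0)) stop("gradients must be positive")
  one <- function(d, sd_frac) {
    y <- i0 * exp(-d * gradients^2)
    if (sd_frac > 0) y <- y + stats::rnorm(length(gradients), 0, sd_frac * i0)
    out <- data.frame(x = gradients^2, intensity = y,
                      err = rep(sd_frac * i0, length(gradients)))
    attr(out, "x_kind") <- "grad2_gcm2"
    out
  }
  if (!is.null(d_atten)) {
    return(.with_seed(seed, one(d_atten, noise_frac)))
  }
  stopifnot(inherits(truth, "ground_truth"))
  .with_seed(seed, {
    protein <- lapply(truth$residues, function(r) {
      one(truth$diffusion$d_protein, noise_frac)
    })
    names(protein) <- as.character(truth$residues)
    list(protein = protein,
         reference = one(truth$diffusion$d_reference, reference_noise_frac))
  })
}

#' Simulate a CSP titration
#'
#' Per-residue chemical shift perturbations follow the exact single-site
#' quadratic binding isotherm at the ground-truth `Kd` and saturation CSP.
#'
#' @param truth a [ground_truth()] object.
#' @param ligand_points total ligand concentrations, non-decreasing and
#'   starting at 0, same unit as `truth$titration$p_total`.
#' @param noise_sd optional Gaussian noise on the CSPs, ppm.
#' @param seed RNG seed.
#' @return data.frame (`residue`, `ligand`, `csp`).
#' @export
gen_titration <- function(truth,
                          ligand_points = truth$titration$p_total *
                            c(0, 0.25, 0.5, 0.75, 1, 1.5, 2, 3),
                          noise_sd = 0, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (any(ligand_points < 0)) stop("ligand concentrations must be >= 0")
  if (is.unsorted(ligand_points)) stop("ligand_points must be non-decreasing")
  if (ligand_points[1] != 0) stop("the titration must start at zero ligand")
  tt <- truth$titration
  grid <- expand.grid(ligand = ligand_points, residue = truth$residues,
                      KEEP.OUT.ATTRS = FALSE)[, c("residue", "ligand")]
  f <- binding_fraction(grid$ligand, tt$p_total, tt$kd)
  grid$csp <- f * tt$ddmax_ppm[match(grid$residue, truth$residues)]
  if (noise_sd > 0) {
    grid$csp <- grid$csp +
      .with_seed(seed, stats::rnorm(nrow(grid), 0, noise_sd))
    grid$csp[grid$ligand == 0] <- 0   # CSP is defined relative to apo
  }
  rownames(grid) <- NULL
  grid
}

#' Simulate a backbone amide relaxation dataset
#'
#' R1, R2 and the heteronuclear NOE are back-calculated from the
#' Lipari-Szabo spectral density at the ground-truth order parameters,
#' internal correlation times and global rotational correlation time
#' ([predict_rates()]), at one or more static fields.
#'
#' @param truth a [ground_truth()] object.
#' @param fields 1H Larmor frequencies, MHz (non-empty).
#' @param noise_frac fractional Gaussian noise applied to R1 and R2 (and,
#'   as an absolute sd of the same magnitude, to the NOE ratio).
#' @param seed RNG seed.
#' @return data.frame (`residue`, `field`, `r1`, `r1_err`, `r2`, `r2_err`,
#'   `noe`, `noe_err`).
#' @export
gen_modelfree_rates <- function(truth, fields = 800, noise_frac = 0,
                                seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (length(fields) == 0) stop("at least one field is required")
  mf <- truth$modelfree
  if (any(mf$s2 < 0 | mf$s2 > 1)) stop("S2 must lie in [0, 1]")
  rows <- expand.grid(residue = truth$residues, field = fields,
                      KEEP.OUT.ATTRS = FALSE)
  idx <- match(rows$residue, truth$residues)
  pr <- predict_rates(mf$s2[idx], mf$tau_c_ns, mf$tau_e_ps[idx], rows$field)
  rows$r1 <- pr$r1; rows$r2 <- pr$r2; rows$noe <- pr$noe
  .with_seed(seed, {
    n <- nrow(rows)
    if (noise_frac > 0) {
      rows$r1 <- rows$r1 * (1 + stats::rnorm(n, 0, noise_frac))
      rows$r2 <- rows$r2 * (1 + stats::rnorm(n, 0, noise_frac))
      rows$noe <- rows$noe + stats::rnorm(n, 0, noise_frac)
    }
    rows$r1_err <- noise_frac * abs(pr$r1)
    rows$r2_err <- noise_frac * abs(pr$r2)
    rows$noe_err <- rep(noise_frac, n)
    rows
  })
}

#' Simulate a gridded 2D spectral plane with Gaussian peaks
#'
#' Builds a dense intensity matrix (1H x 15N) containing two-dimensional
#' Gaussian peaks at the positions of a peak list. Intended for testing the
#' box-sum quantification; it does not emulate realistic lineshapes,
#' truncation wiggles or noise correlations of processed spectra.
#'
#' @param peaks data.frame with columns `residue`, `h_ppm`, `n_ppm` and
#'   optionally `amp` (default 100).
#' @param h_range,n_range ppm ranges (decreasing ppm with increasing index,
#'   as spectra are usually drawn, is allowed).
#' @param np number of points c(1H, 15N).
#' @param linewidth_ppm Gaussian sigma c(1H, 15N) in ppm.
#' @param noise_sd additive Gaussian noise per grid point.
#' @param meta plane metadata (e.g. `list(kind = "delay_s", value = 0.05)`).
#' @param seed RNG seed.
#' @return a [gridded_plane()] object.
#' @export
gen_plane <- function(peaks, h_range = c(10.5, 5.5), n_range = c(132, 102),
                      np = c(256, 128), linewidth_ppm = c(0.02, 0.15),
                      noise_sd = 0, meta = list(), seed = NULL) {
  stopifnot(all(c("h_ppm", "n_ppm") %in% names(peaks)))
  amp <- peaks$amp %||% rep(100, nrow(peaks))
  h <- seq(h_range[1], h_range[2], length.out = np[1])
  nn <- seq(n_range[1], n_range[2], length.out = np[2])
  z <- matrix(0, np[1], np[2])
  for (k in seq_len(nrow(peaks))) {
    gh <- exp(-(h - peaks$h_ppm[k])^2 / (2 * linewidth_ppm[1]^2))
    gn <- exp(-(nn - peaks$n_ppm[k])^2 / (2 * linewidth_ppm[2]^2))
    z <- z + amp[k] * outer(gh, gn)
  }
  if (noise_sd > 0) {
    z <- z + .with_seed(seed, matrix(stats::rnorm(length(z), 0, noise_sd),
                                     nrow(z), ncol(z)))
  }
  gridded_plane(z, h, nn, meta = meta)
}

#' Simulate a compact globular all-atom coordinate set
#'
#' Generates a synthetic protein-like atom cloud: residues laid out as a
#' self-avoiding cluster of pseudo side-chain groups uniformly filling a
#' sphere. A uniform ball of radius R has a radius of gyration
#' `R * sqrt(3/5)`, so the target Rg fixes the sphere radius. This is a
#' synthetic stand-in used by tests and examples; it is not a real
#' structure.
#'
#' @param n_res number of residues (~8 atoms each).
#' @param rg_target target radius of gyration, Angstrom.
#' @param seed RNG seed.
#' @return an `atom_set` data.frame as returned by [load_structure()].
#' @export
gen_globular_atoms <- function(n_res = 160, rg_target = 15.4, seed = 1) {
  R <- rg_target / sqrt(3 / 5)
  .with_seed(seed, {
    n_atoms <- n_res * 8
    ## uniform sampling in a ball of radius R
    u <- stats::runif(n_atoms)
    r <- R * u^(1 / 3)
    z <- stats::rnorm(n_atoms); y <- stats::rnorm(n_atoms)
    x <- stats::rnorm(n_atoms)
    nrm <- sqrt(x^2 + y^2 + z^2)
    ele <- sample(c("C", "N", "O", "H", "S"), n_atoms, replace = TRUE,
                  prob = c(0.32, 0.08, 0.12, 0.47, 0.01))
    atoms <- data.frame(
      element = ele,
      name = ele,
      resno = rep(seq_len(n_res), length.out = n_atoms),
      aa = "ALA",
      chain = "A",
      x = r * x / nrm, y = r * y / nrm, z = r * z / nrm,
      occupancy = 1,
      mass = .atomic_mass(ele),
      is_protein = TRUE,
      stringsAsFactors = FALSE)
    class(atoms) <- c("atom_set", "data.frame")
    atoms
  })
}
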