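---
title: "Methods: quantifying protein dynamics and compactness from solution NMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying protein dynamics and compactness from solution NMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrdyn)
```

This vignette records the models behind each analysis stage, the tunable
parameters and their defaults, what the synthetic-data generators do and do
not emulate, and the numerical decisions taken where the design was
genuinely open.

## The scientific setting

A small globular protein (think of a ~17 kDa, ~160-residue ligand-binding
protein) is studied with and without a ligand in its binding cavity. Four
independent classes of solution-NMR observables report on whether binding
rigidifies the backbone and compacts the average structure:

1. **Backbone amide relaxation** (R1, R1ρ-derived R2, heteronuclear NOE)
   probes picosecond–nanosecond motion via the order parameter S² and
   yields the rotational correlation time τc, itself a hydrodynamic probe.
2. **CPMG relaxation dispersion** probes microsecond–millisecond
   conformational exchange: the dependence of the effective transverse
   rate R2,eff on the pulsing frequency ν_CPMG encodes the population pA,
   rate kex and chemical-shift separation Δω of an exchange process.
3. **Pulsed-field-gradient diffusion** measures the translational
   diffusion coefficient, hence the hydrodynamic radius via
   Stokes–Einstein.
4. **Chemical shifts** locate binding (CSP titrations, Δω_cum between apo
   and bound shift tables) and, through the correlation of
   dispersion-derived Δω with binding-induced shift changes, test whether
   the apo ensemble already samples bound-like conformers.

## Relaxation and model-free analysis

Decay series are fit as `I(x) = I0 exp(−rate·x)` by Levenberg–Marquardt
least squares with log-linear initialisation; negative best-fit rates are
reported with a warning, never clamped, because they are diagnostic of
pathological series. The tilted-frame correction
`R2 = R1ρ/sin²θ − R1/tan²θ` takes the spin-lock tilt angle θ as user
input with default 90° (on-resonance), since off-resonance parameters are
acquisition-specific.

Model-free analysis uses the simple Lipari–Szabo spectral density with
isotropic overall tumbling — one global τc — and conventional physical
constants: N–H bond length 1.02 Å, ¹⁵N CSA −160 ppm, standard
gyromagnetic ratios. Exchange broadening (Rex) is deliberately *not* a
model-free parameter: residues with dispersion-detected exchange belong to
the CPMG analysis, keeping the two timescale windows cleanly separated.

τc is first estimated from the trimmed mean (25% per tail) of R2/R1
ratios of rigid residues (NOE ≥ 0.65). Trimming makes the estimator
robust to a minority of exchange-inflated R2 values; the suite verifies
3%-accuracy under 20% contamination. The plain ratio estimator is biased
slightly low (about 2% at τe = 50 ps) because fast internal motion
perturbs R1 and R2 unequally; `fit_tc(refine = TRUE)` removes this by
minimising the total per-residue model-free χ² over τc, the strategy of
global model-free software. Per-residue fits compare S²-only against
S² + τe by an F-test at α = 0.05 (one added parameter); with noiseless
input the round trip S² → rates → S² is exact to the optimiser tolerance.
S² is constrained to [0, 1] and boundary solutions are flagged. When no
experimental errors are supplied, relative weights (1/y²) are used so that
the NOE (≈0.8) is not drowned out by R2 (≈15 s⁻¹).

## CPMG dispersion: closed form versus propagation

Peak intensities convert to effective rates as
`R2,eff = −ln(I/I0)/T_relax` with T_relax = 30 ms; repeat points (67 and
600 Hz in the default grid) provide a per-curve error estimate (half the
absolute repeat difference) when no other estimate exists.

Two forward models are implemented:

- `carver_richards_r2eff()` — the closed form for two-state exchange with
  equal intrinsic rates, in the `cosh⁻¹(D₊cosh η₊ − D₋cos η₋)` form with
  `ψ = kex² − Δω²`, `ζ = −2Δω·kex(pA−pB)`, evaluated at
  τcp = 1/(2ν_CPMG). Large η₊ is handled in the log domain
  (`acosh x ≈ ln 2x`), so the expression never overflows.
- `bloch_mcconnell_r2eff()` — exact propagation of the two-state complex
  transverse magnetisation through the finite echo train (ideal 180°
  pulses as complex conjugation), via a closed-form eigendecomposition of
  the two-echo propagator. It requires an even, whole number of echoes in
  T_relax, which every frequency of the default grid satisfies.

These two are *not* the same thing at short trains. The closed form is the
asymptotic (many-echo) eigenvalue decay rate; the propagation of a 30 ms
train at ν_CPMG = 33 Hz contains just two echoes, and the finite-train
amplitude factor then shifts R2,eff by up to tens of percent of the
dispersion amplitude in the slow-exchange corner (kex ≲ Δω). The suite
quantifies this relationship from both ends: the two models agree within
2% of the dispersion amplitude across the full validation grid
(pA 0.9–0.99, kex 100–3000 s⁻¹, Δω 0.5–4 ppm at 800 MHz) once the train
is long (T = 480 ms), and the deviation shrinks monotonically with train
length. The fast-exchange propagation also matches the Luz–Meiboom closed
form within 1%.

Consequently `fit_dispersion()` exposes both: `model = "cr"` (default) is
the fast closed form, appropriate for real data and literature
comparability; `model = "bm"` fits the exact finite-train propagation and
is the right choice whenever the data are known to come from a finite echo
train — in particular for round-trip validation against
`gen_cpmg_dataset()`, which simulates the train exactly. Fitting the
closed form to propagator-generated 30 ms data biases kex upward by
roughly 15–20%; the tests therefore use `model = "bm"` for parameter
recovery, where the fit is exact to ~1e-9 on noiseless data.

The global fit shares (pA, kex) across residues and fields and one |Δω|
per residue in ppm (scaled to rad/s by each field's ¹⁵N frequency);
per-residue/per-field intrinsic rates R2,0 enter the model additively and
are profiled analytically, so the nonlinear search runs over 2 + R
parameters only. Multi-start initialisation covers kex ∈ {50…5000} s⁻¹
(8 log-spaced points) × pA ∈ {0.9, 0.95, 0.99}; Δω starts from the
fast-limit amplitude relation. Δω signs are not identifiable from CPMG
alone, so magnitudes are reported. Parameter errors and 95% intervals come
from ≥100 Monte-Carlo draws: data resampled around the fitted curve from
the per-point errors, refit warm-started from the optimum. The exchange
lifetime is reported as τ_ex = 1/kex in ms with its propagated error. A
fit drifting to pA ≈ 0.5 with tiny Δω is flagged as degenerate.

Flat-profile detection compares a weighted constant model against the
fast-limit exchange form (parameters R2,0, φ = pA·pB·Δω², kex; R2,0
profiled, grid + simplex for the rest) with an F-test at α = 0.01. Because
the alternative is boundary-constrained (φ ≥ 0) and kex is only partly
identifiable under the null, the test is conservative; the suite measures
the false-positive rate by simulation (≤ α plus the binomial margin of the
simulation size) and full power at a 5 s⁻¹ amplitude with 0.3 s⁻¹ noise.

## Diffusion and hydrodynamics

Stimulated-echo intensities are fit as `I(G) = I0 exp(−d·G²)`. The
gradient timing factors (γ²δ²(Δ−δ/3)-type) are folded into d because the
internal reference, measured under identical conditions, cancels them:
`r_h = r_ref · d_ref/d_protein` with r_ref = 2.12 Å for dioxane. Absolute
Dt values come from Stokes–Einstein, `Dt = kBT/(6πη·r_h)` (298 K,
η = 0.891 mPa·s defaults). Sample-to-sample comparisons use the ratio of
the mean attenuation of the 20 best-fit residues (smallest fit RMSD, ties
broken by ascending residue number for determinism), with the error as the
quadrature of the two aggregate SDs — mirroring error bars that are SDs
over the selected residues.

## Chemical-shift analytics

`Δω_cum = sqrt((1/N) Σ (Δω_i/ω_i,std)²)` runs over the nuclei (¹H^N,
¹⁵N, ¹³C′, ¹³Cα, ¹³Cβ) available in *both* tables; N ≤ 5 counts only
those, and residues with no shared nucleus are dropped, not zero-filled.
The normalisation factors ω_i,std (one SD of each nucleus's shift
distribution across deposited assignments) ship as a fixed, overridable
table — `c(h = 0.65, n = 4.7, co = 1.8, ca = 2.6, cb = 5.3)` ppm — so the
analysis needs no database access. Combined amide CSPs use
`sqrt(ΔH² + (0.154·ΔN)²)`, the conventional gyromagnetic weighting.

Titrations are fit to the exact single-site quadratic isotherm
`f = ((P+L+Kd) − sqrt((P+L+Kd)² − 4PL))/(2P)`, CSP = f·Δδ_max. The
saturation CSP enters linearly and is profiled; Kd is searched in 1-D on
the log scale, which is robust in the tight-binding regime (Kd ≪ P) where
the gradient with respect to Kd is nearly singular. Titrations reaching
<80% saturation are flagged as poorly constraining Kd. Ligands binding
with 1:2 stoichiometry are *not* modelled by a two-site equation:
per-residue single-site fits resolve the sites spatially, which is how
per-residue CSP data are normally interpreted. The dispersion-versus-
binding comparison (`correlate_dw`) uses Pearson correlation on
magnitudes plus a through-origin slope.

## Structure compactness

`radius_of_gyration()` computes `sqrt(Σw_i|r_i − r̄|²/Σw_i)` over ATOM
records of the 20 standard amino acids (hydrogens included when present),
with atomic-mass weights by default; since depositions differ in whether
Rg values are mass-weighted, both variants are reported by `rg_report()`.
Alternate locations are resolved by highest occupancy (ties: first), a
deterministic choice preferred over occupancy-weighted averaging. PDB
parsing is delegated to bio3d.

## The synthetic-data generators

Every generator is a deterministic function of (parameters, seed); seeds
are explicit arguments, never global state, and the caller's RNG stream is
left untouched. Defaults copy the acquisition conditions of the study the
package emulates: two fields (500/800 MHz), ν_CPMG from 33 to 933 Hz with
repeats at 67 and 600 Hz and T_relax = 30 ms, R1 delays 10.9–870.4 ms,
R1ρ delays 10–100 ms, gradients 22–58 G/cm, a 0.2 mM protein titrated to
a 3-fold ligand excess. The exchange ground truth is a single process with
τ_ex = 3.5 ms and per-residue Δω of 0.3–1.0 ppm; pA = 0.95 was chosen
once as a typical sparsely populated minor state (the population is not
independently constrained by the emulated observables). Model-free truth:
τc = 8.7 ns (apo-like) or 8.4 ns (bound-like), S² = 0.85, τe = 50 ps.
Diffusion truth fixes d_ref/d_protein = 20.1/2.12 so the apo protein has a
20.1 Å hydrodynamic radius against the dioxane reference; the reference
series carries 20-fold lower fractional noise than the amide series, since
the reference resonance is far more intense than any single amide peak.

Noise is independent Gaussian per point — as an absolute SD for rates
(matching the repeat-experiment convention) and as a fraction of I0 for
intensities. The generators do **not** emulate lineshapes, baseline or
phase artefacts, correlated noise, peak overlap, convection, off-resonance
or finite-pulse CPMG effects, or anisotropic tumbling. Passing round-trip
tests therefore demonstrates correctness of the estimators under the
stated noise model, not robustness to every artefact of real spectra. The
2D-plane generator produces plain Gaussian peaks and exists to exercise
the box-sum quantifier; `gen_globular_atoms()` produces a synthetic
protein-like atom cloud (uniform ball, Rg = R√(3/5)) and is labelled
synthetic — it stands in for real coordinates only where geometry, not
biology, is being tested.

## Numerical choices and degenerate inputs

- Box-sum quantification snaps the box centre to the local intensity
  maximum within ±1 grid point per plane (peak maxima drift between
  planes); boxes crossing the grid edge raise an error rather than
  truncate; no interpolation or overlap correction is applied.
- Non-positive CPMG intensities (vanished peaks) drop to NA with a
  warning instead of producing infinite rates.
- `detect_flat` returns statistic 0 for an exactly constant curve.
- The propagation model perturbs exactly-degenerate eigenvalues by 1e-9
  and falls back to explicit echo iteration in the (rare) ill-conditioned
  lanes.
- All tabular I/O is TSV with one header line, UTF-8, '.' decimals;
  rerunning a configuration with the same seeds reproduces every table
  bit-identically. Logs go to stderr and are never mixed into results.

## Problem sizes used by the test suite

The suite runs 8-residue, two-field dispersion studies (272 points each);
50 replicates with 100 Monte-Carlo draws each for interval coverage; 500
replicates for estimator-bias checks; 500 null curves for the flatness
false-positive rate; and a 240-point parameter grid for the closed-form /
propagation comparison. These sizes were chosen so that each statistical
assertion has enough replicates for its binomial or mean-error margin
while the whole suite stays comfortably runnable on a laptop.

## Known limitations

- Two-state exchange only; no three-state or off-resonance R1ρ models.
- Isotropic rotational diffusion only; no axially symmetric tensor, no
  extended (two-timescale) model-free.
- Single-site binding isotherm; no explicit multi-site model.
- Mono-exponential decays only; no bi-exponential or stretched fits.
- The flatness F-test's null calibration is simulation-verified for the
  default grid; very short curves (n close to 4) leave few denominator
  degrees of freedom and the test loses power accordingly.
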