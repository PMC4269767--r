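# nmrdyn

Solution-state NMR analysis of protein conformational dynamics and
hydrodynamic compactness, built around the question of what ligand binding
does to a small globular protein: does the backbone rigidify, and does the
average structure compact? The package implements the complete quantitative
pipeline for answering it from per-residue NMR observables:

- **Relaxation fitting** — mono-exponential fits of R1 and R1ρ decay
  series, tilted-frame correction `R2 = R1ρ/sin²θ − R1/tan²θ`, and
  heteronuclear ¹H→¹⁵N NOE ratios with error propagation.
- **Model-free analysis** — the Lipari–Szabo spectral density
  `J(ω) = (2/5)[S²τc/(1+ω²τc²) + (1−S²)τ/(1+ω²τ²)]`, back-calculation of
  (R1, R2, NOE) from standard ¹⁵N dipolar/CSA expressions, a global
  rotational correlation time τc from trimmed R2/R1 ratios, and
  per-residue S²/τe fits with F-test model selection.
- **CPMG relaxation dispersion** — conversion of peak intensities to
  `R2,eff = −ln(I/I0)/T_relax`, the Carver–Richards closed form for
  two-state exchange, an exact Bloch–McConnell echo-train propagator, an
  F-test for flat profiles, and a global two-field fit sharing (pA, kex)
  across residues with per-residue Δω (ppm) and Monte-Carlo parameter
  errors.
- **PFG diffusion** — Stejskal–Tanner-type attenuation fits
  `I(G) = I0·exp(−dG²)`, top-20 best-fit aggregation, hydrodynamic radii
  against an internal dioxane reference (r_h = 2.12 Å), and
  Stokes–Einstein conversion `Dt = kBT/(6πηr_h)`.
- **Chemical shifts** — cumulative shift differences
  `Δω_cum = sqrt((1/N)Σ(Δω_i/ω_i,std)²)` over up to five backbone nuclei,
  combined amide CSPs, exact single-site quadratic binding isotherm fits
  for Kd, and the correlation between dispersion-derived and
  binding-induced shift differences.
- **Structure** — PDB import (via bio3d) and mass-weighted or unweighted
  radii of gyration over protein atoms.
- **Synthetic data** — generators for every observable above with known
  ground truth, explicit seeds and acquisition-realistic grids, so the
  entire pipeline is testable without spectrometer data.

Fitting functions return classed S3 objects (`decay_fit`, `exchange_fit`,
`modelfree_fit`, `kd_fit`) with `print`, `coef`, `predict` and `plot`
methods.

## Worked example

Simulate a two-field dispersion experiment for eight residues undergoing a
single millisecond exchange process, and refit it globally:

```r
library(nmrdyn)

truth <- ground_truth()        # pA=0.95, kex=286 s^-1, |dw| 0.3-1.0 ppm
data <- gen_cpmg_dataset(truth, fields = c(500, 800),
                         noise_sd = 0.3, seed = 7)
fit <- fit_dispersion(data, model = "bm", n_mc = 100, seed = 7)
fit
#> Global two-state exchange fit (Bloch-McConnell propagation)
#>   pA     = 0.9479 +/- 0.0036
#>   kex    = 271.1 s^-1 +/- 19.6
#>   tau_ex = 3.69 ms +/- 0.27
#>   8 residues, 2 fields (500/800 MHz), reduced chi2 = 1.050
```

The exchange lifetime τ_ex = 1/kex is recovered within its Monte-Carlo
error of the true 3.5 ms, and `fit$residues` holds the per-residue |Δω| in
ppm with 95% intervals. A hydrodynamic example:

```r
stokes_einstein(2.12)                        # dioxane: 1.1555e-09 m^2/s
100 * (stokes_einstein(19.3) / stokes_einstein(20.1) - 1)
#> [1] 4.145078   # % diffusion acceleration for a 20.1 -> 19.3 A compaction
```

An end-to-end apo-versus-bound comparison (order parameters, flat/non-flat
dispersion counts, Dt ratio, Δω_cum profile, shift correlation) runs
through `study_config()` + `run_compare()`; see the methods vignette.

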