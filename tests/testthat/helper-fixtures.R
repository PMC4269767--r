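# Shared fixtures, built in code.

# small two-field dispersion truth used across cpmg tests
disp_truth <- function(...) {
  ground_truth(residues = 1:8, pa = 0.95, kex = 1000 / 3.5,
               dw_ppm = seq(0.3, 1.0, length.out = 8),
               r2_0 = c("500" = 13, "800" = 16), ...)
}

# hand-rolled reference Rg: direct translation of the definition,
# independent of the package implementation
rg_direct <- function(xyz, w) {
  ctr <- colSums(xyz * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(xyz, 2, ctr)^2)) / sum(w))
}

# independent spectral-density evaluation (plain arithmetic, no reuse)
j_direct <- function(omega, s2, tc, te) {
  tau <- if (te > 0) 1 / (1 / tc + 1 / te) else 0
  term2 <- if (tau > 0) (1 - s2) * tau / (1 + (omega * tau)^2) else 0
  (2 / 5) * (s2 * tc / (1 + (omega * tc)^2) + term2)
}
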