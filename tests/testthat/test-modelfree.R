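test_that("spectral density matches an independent evaluation and its limits", {
  expect_equal(spectral_density(0, 1, 8.7e-9), 0.4 * 8.7e-9)
  # S2 = 0 with vanishing tau_e: J -> 0 at every frequency
  expect_true(all(spectral_density(c(0, 5e8, 1e9), 0, 1e-8, 1e-16) < 1e-16))

  # sweep against the independently coded closed form
  for (s2 in c(0, 0.3, 0.85, 1)) {
    for (te in c(0, 20e-12, 500e-12)) {
      w <- seq(0, 6e9, length.out = 25)
      expect_equal(spectral_density(w, s2, 8.7e-9, te),
                   vapply(w, j_direct, numeric(1), s2 = s2, tc = 8.7e-9,
                          te = te),
                   tolerance = 1e-12)
    }
  }
  # J >= 0 and monotone non-increasing in |omega|
  w <- seq(0, 1e10, length.out = 200)
  j <- spectral_density(w, 0.6, 8.7e-9, 50e-12)
  expect_true(all(j >= 0))
  expect_true(all(diff(j) <= 1e-20))
})

test_that("back-calculated rates match an independent computation at both fields", {
  # independent arithmetic with the same conventional constants
  gamma_h <- 2.6752218744e8; gamma_n <- -2.7126180436e7
  for (f in c(500, 800)) {
    wh <- 2 * pi * f * 1e6
    wn <- wh * abs(gamma_n / gamma_h)
    dcon <- 1e-7 * 1.054571817e-34 * gamma_h * abs(gamma_n) / (1.02e-10)^3
    c2 <- (wn * 160e-6)^2 / 3
    s2 <- 0.85; tc <- 8.7e-9; te <- 50e-12
    jj <- function(w) j_direct(w, s2, tc, te)
    r1 <- dcon^2 / 4 * (jj(wh - wn) + 3 * jj(wn) + 6 * jj(wh + wn)) +
      c2 * jj(wn)
    r2 <- dcon^2 / 8 * (4 * jj(0) + jj(wh - wn) + 3 * jj(wn) + 6 * jj(wh) +
                          6 * jj(wh + wn)) + c2 / 6 * (4 * jj(0) + 3 * jj(wn))
    noe <- 1 + dcon^2 / 4 * (gamma_h / gamma_n) *
      (6 * jj(wh + wn) - jj(wh - wn)) / r1
    p <- predict_rates(0.85, 8.7, 50, f)
    expect_equal(p$r1, r1, tolerance = 1e-10)
    expect_equal(p$r2, r2, tolerance = 1e-10)
    expect_equal(p$noe, noe, tolerance = 1e-10)
  }
  # rigid rotor at 800 MHz: NOE positive and below 1
  p <- predict_rates(1, 8.7, 0, 800)
  expect_gt(p$noe, 0); expect_lt(p$noe, 1)
  # R2 grows with tau_c (J(0) dominance)
  expect_gt(predict_rates(1, 8.7, 0, 800)$r2,
            predict_rates(1, 8.4, 0, 800)$r2)
})

test_that("tau_c estimation: exact on rigid rotors, robust to exchange contamination", {
  rigid <- ground_truth(residues = 1:20, s2 = 1, tau_e_ps = 0)
  r <- gen_modelfree_rates(rigid, fields = c(500, 800))
  expect_equal(fit_tc(r)$tau_c_ns, 8.7, tolerance = 1e-4)

  # 20% of residues with exchange-inflated R2: trimmed estimator holds
  r_bad <- r
  hit <- r_bad$residue %in% 1:4
  r_bad$r2[hit] <- r_bad$r2[hit] + 8
  expect_lt(abs(fit_tc(r_bad)$tau_c_ns - 8.7) / 8.7, 0.03)

  # with internal motion the refined estimator recovers the truth
  soft <- ground_truth(residues = 1:8, s2 = 0.85, tau_e_ps = 50)
  rs <- gen_modelfree_rates(soft, fields = c(500, 800))
  tc <- fit_tc(rs, refine = TRUE)
  expect_equal(tc$tau_c_ns, 8.7, tolerance = 0.05 / 8.7)
  expect_error(fit_tc(r[1:3, ]), "fewer than 5")
})

test_that("per-residue model-free fits recover the ground truth", {
  rigid <- ground_truth(residues = 1:6, s2 = 1, tau_e_ps = 0)
  mf <- fit_modelfree(gen_modelfree_rates(rigid, fields = 800), 8.7)
  expect_equal(mf$residues$s2, rep(1, 6), tolerance = 1e-3)
  expect_true(all(mf$residues$model == "s2"))

  soft <- ground_truth(residues = 1:4, s2 = 0.85, tau_e_ps = 50)
  rates <- gen_modelfree_rates(soft, fields = c(500, 800))
  mf2 <- fit_modelfree(rates, 8.7)
  expect_equal(mf2$residues$s2, rep(0.85, 4), tolerance = 1e-3)
  expect_equal(mf2$residues$tau_e_ps, rep(50, 4), tolerance = 0.05 * 50)

  # 1% noise: both parameters within 5%
  noisy <- gen_modelfree_rates(soft, fields = c(500, 800),
                               noise_frac = 0.01, seed = 21)
  mf3 <- fit_modelfree(noisy, 8.7)
  expect_lt(max(abs(mf3$residues$s2 - 0.85) / 0.85), 0.05)
  expect_lt(max(abs(mf3$residues$tau_e_ps - 50) / 50), 0.4)
})

test_that("sliding-window averaging uses +/- half_width residues", {
  res <- 1:10
  val <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  sm <- sliding_mean(res, val, half_width = 2)
  expect_equal(sm[3], mean(1:5))
  expect_equal(sm[1], mean(1:3))
  expect_equal(sm[10], mean(8:10))
})
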