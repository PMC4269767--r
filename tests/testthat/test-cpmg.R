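test_that("intensity-to-rate conversion is exact and propagates errors", {
  expect_equal(r2eff_from_intensities(80, 80, 0.030)$r2eff, 0)
  expect_equal(r2eff_from_intensities(100 * exp(-0.45), 100, 0.030)$r2eff,
               15, tolerance = 1e-12)
  e <- r2eff_from_intensities(50, 100, 0.030, intensity_err = 1, i0_err = 2)
  expect_equal(e$r2eff_err, sqrt((1 / 50)^2 + (2 / 100)^2) / 0.030)
  expect_warning(out <- r2eff_from_intensities(c(50, -3), 100, 0.030),
                 "non-positive")
  expect_true(is.na(out$r2eff[2]) && !is.na(out$r2eff[1]))
})

test_that("repeat points yield the half-difference error convention", {
  d <- data.frame(residue = 1, field = 500,
                  nu_cpmg = c(66.7, 66.7, 600, 600, 200),
                  r2eff = c(15.0, 15.8, 13.0, 12.6, 14.0))
  out <- repeat_errors(d)
  expect_equal(unique(out$r2eff_err), mean(c(0.4, 0.2)))
  d2 <- data.frame(residue = 1, field = 500, nu_cpmg = c(100, 200, 300),
                   r2eff = c(1, 2, 3))
  expect_error(repeat_errors(d2), "repeat")
})

test_that("Carver-Richards closed form: degenerate limits and numerical safety", {
  nu <- default_nu_cpmg()
  expect_equal(carver_richards_r2eff(0.95, 500, 0, 12, nu), rep(12, length(nu)))
  expect_equal(carver_richards_r2eff(1, 500, 800, 12, nu), rep(12, length(nu)))
  # huge kex: log-domain branch, no overflow, fast-exchange limit ~ R2_0
  big <- carver_richards_r2eff(0.9, 1e6, 200, 12, nu)
  expect_true(all(is.finite(big)))
  expect_equal(big, rep(12, length(nu)), tolerance = 0.01)
  # monotone non-increasing in nu over the validation grid
  for (pa in c(0.9, 0.99)) {
    for (kex in c(100, 1000, 3000)) {
      for (dw in ppm_to_rads(c(0.5, 4), 800)) {
        r <- carver_richards_r2eff(pa, kex, dw, 12, sort(unique(nu)))
        expect_true(all(diff(r) <= 1e-8))
      }
    }
  }
})

test_that("propagation oracle: no-exchange identity, echo timing and fast-exchange limit", {
  nu <- default_nu_cpmg()
  expect_equal(bloch_mcconnell_r2eff(1, 0, 800, 12, nu), rep(12, length(nu)),
               tolerance = 1e-12)
  expect_error(bloch_mcconnell_r2eff(0.95, 500, 800, 12, 170, 0.030),
               "even")
  lm_ <- luz_meiboom_r2eff(0.9, 5000, ppm_to_rads(0.5, 500), 10, nu)
  bm <- bloch_mcconnell_r2eff(0.9, 5000, ppm_to_rads(0.5, 500), 10, nu)
  expect_lt(max(abs(lm_ - bm) / bm), 0.01)
})

test_that("closed form is the long-train limit of the propagation over the validation grid", {
  nu <- default_nu_cpmg()
  grid <- expand.grid(pa = c(0.9, 0.95, 0.99),
                      kex = exp(seq(log(100), log(3000), length.out = 5)),
                      dw_ppm = c(0.5, 1.5, 4))
  dev_long <- dev_short <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    dw <- ppm_to_rads(g$dw_ppm, 800)
    cr <- carver_richards_r2eff(g$pa, g$kex, dw, 12, nu)
    bm_long <- bloch_mcconnell_r2eff(g$pa, g$kex, dw, 12, nu, 0.480)
    bm_short <- bloch_mcconnell_r2eff(g$pa, g$kex, dw, 12, nu, 0.030)
    amp_l <- max(max(bm_long) - min(bm_long), 1e-6)
    amp_s <- max(max(bm_short) - min(bm_short), 1e-6)
    dev_long[i] <- max(abs(cr - bm_long)) / amp_l
    dev_short[i] <- max(abs(cr - bm_short)) / amp_s
  }
  # agreement within 2% of the dispersion amplitude for a long echo train
  expect_lt(max(dev_long), 0.02)
  # and the deviation shrinks as the train lengthens (many-echo limit)
  expect_gt(mean(dev_short > dev_long), 0.95)
})

test_that("flatness detection distinguishes null from dispersive curves", {
  nu <- default_nu_cpmg()
  set.seed(301)
  null_curve <- 15 + rnorm(length(nu), 0, 0.3)
  expect_true(detect_flat(nu, null_curve, rep(0.3, length(nu)))$flat)

  disp <- bloch_mcconnell_r2eff(0.95, 1000 / 3.5, ppm_to_rads(0.9, 500),
                                13, nu, 0.030) + rnorm(length(nu), 0, 0.3)
  expect_false(detect_flat(nu, disp, rep(0.3, length(nu)))$flat)

  const <- detect_flat(nu, rep(14, length(nu)))
  expect_true(const$flat)
  expect_equal(const$statistic, 0)
  expect_error(detect_flat(c(100, 200, 300), c(1, 2, 3)), "4")
})

test_that("global fit recovers ground truth on noiseless two-field data", {
  truth <- disp_truth()
  d0 <- gen_cpmg_dataset(truth, noise_sd = 0)
  f <- fit_dispersion(d0, model = "bm", n_mc = 0)
  expect_equal(f$pa, truth$exchange$pa, tolerance = 1e-3)
  expect_equal(f$kex, truth$exchange$kex, tolerance = 1e-3)
  expect_equal(f$residues$dw_ppm, truth$exchange$dw_ppm, tolerance = 1e-3)
  expect_equal(f$r2_0$r2_0,
               unname(truth$exchange$r2_0[as.character(f$r2_0$field)]),
               tolerance = 1e-3)
  expect_equal(f$tau_ex_ms, 3.5, tolerance = 1e-3)
})

test_that("global fit reporting: chi2 never above the flat model, methods work", {
  truth <- disp_truth()
  d <- gen_cpmg_dataset(truth, noise_sd = 0.3, seed = 9)
  f <- fit_dispersion(d, model = "bm", n_mc = 25, seed = 10)

  # weighted flat-model chi2 per curve
  w <- 1 / d$r2eff_err^2
  key <- interaction(d$residue, d$field)
  chi2_flat <- sum(unlist(lapply(split(seq_len(nrow(d)), key), function(i) {
    mu <- sum(w[i] * d$r2eff[i]) / sum(w[i])
    w[i] * (d$r2eff[i] - mu)^2
  })))
  expect_lt(f$chi2, chi2_flat)

  expect_equal(unname(coef(f)[["pa"]]), f$pa)
  expect_output(print(f), "tau_ex")
  pr <- predict(f, data.frame(residue = 1, field = 800,
                              nu_cpmg = c(100, 900)))
  expect_true(all(is.finite(pr)) && pr[1] > pr[2])
  # tau_ex is reported in ms with an error from the Monte-Carlo draws
  expect_equal(f$tau_ex_ms, 1000 / f$kex)
  expect_true(is.finite(f$global$tau_ex_err_ms))
})
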