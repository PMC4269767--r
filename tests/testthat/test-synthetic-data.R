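test_that("noiseless CPMG generation equals the propagation oracle and the default grid matches the acquisition", {
  truth <- disp_truth()
  d <- gen_cpmg_dataset(truth, noise_sd = 0)
  dw <- truth$exchange$dw_ppm[match(d$residue, truth$residues)]
  expected <- bloch_mcconnell_r2eff(
    truth$exchange$pa, truth$exchange$kex, ppm_to_rads(dw, d$field),
    truth$exchange$r2_0[as.character(d$field)], d$nu_cpmg, 0.030)
  expect_equal(d$r2eff, expected, tolerance = 1e-12)

  nu <- default_nu_cpmg()
  expect_equal(min(nu), 100 / 3, tolerance = 1e-6)
  expect_equal(max(nu), 2800 / 3, tolerance = 1e-6)
  reps <- unique(nu[duplicated(nu)])
  expect_equal(sort(round(reps)), c(67, 600))
  expect_equal(attr(d, "t_relax"), 0.030)
})

test_that("generators are deterministic functions of (parameters, seed)", {
  truth <- disp_truth()
  expect_identical(gen_cpmg_dataset(truth, noise_sd = 0.4, seed = 5),
                   gen_cpmg_dataset(truth, noise_sd = 0.4, seed = 5))
  expect_identical(gen_relaxation_decays(2, noise_frac = 0.01, seed = 5),
                   gen_relaxation_decays(2, noise_frac = 0.01, seed = 5))
  expect_identical(gen_diffusion_decays(truth, noise_frac = 0.01, seed = 5),
                   gen_diffusion_decays(truth, noise_frac = 0.01, seed = 5))
  a <- gen_cpmg_dataset(truth, noise_sd = 0.4, seed = 5)
  b <- gen_cpmg_dataset(truth, noise_sd = 0.4, seed = 6)
  expect_false(identical(a$r2eff, b$r2eff))
})

test_that("relaxation decay generator honours the stated noise model and delays", {
  d <- gen_relaxation_decays(rate = 2, i0 = 100, delays = c(0, 0.1, 0.5),
                             noise_frac = 0)
  expect_equal(d$intensity[1], 100)
  expect_equal(d$intensity, 100 * exp(-2 * d$x))

  const <- gen_relaxation_decays(rate = 0, noise_frac = 0)
  expect_true(all(const$intensity == const$intensity[1]))

  expect_equal(range(r1_delays()), c(0.0109, 0.8704))
  expect_equal(range(r1rho_delays()), c(0.010, 0.100))
  expect_error(gen_relaxation_decays(rate = -1), "non-negative")
  expect_error(gen_relaxation_decays(2, delays = numeric()), "non-empty")
})

test_that("diffusion decays follow the squared-gradient law", {
  d <- gen_diffusion_decays(d_atten = 1e-3, gradients = c(10, 20, 40),
                            i0 = 50, noise_frac = 0)
  la <- -log(d$intensity / 50)
  # doubling G quadruples the log-attenuation
  expect_equal(la[2] / la[1], 4, tolerance = 1e-10)
  expect_equal(la[3] / la[2], 4, tolerance = 1e-10)
  expect_equal(range(default_gradients()), c(22, 58))
  expect_error(gen_diffusion_decays(d_atten = 1e-3, gradients = c(-5, 10)),
               "positive")
})

test_that("titration generator obeys the binding isotherm limits", {
  truth <- ground_truth(kd = 7e-6, p_total = 2e-4)
  tit <- gen_titration(truth)
  expect_true(all(tit$csp[tit$ligand == 0] == 0))
  # saturation: enormous ligand excess approaches ddmax
  sat <- gen_titration(truth, ligand_points = c(0, truth$titration$p_total * 1e4))
  at_sat <- sat$csp[sat$ligand > 0]
  expect_equal(at_sat, truth$titration$ddmax_ppm, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_error(gen_titration(truth, ligand_points = c(0, -1e-5)), ">= 0")
  expect_error(gen_titration(truth, ligand_points = c(1e-5, 2e-5)), "zero")
})

test_that("model-free rate generator matches the rigid rotor and is monotone in tau_c", {
  rigid <- ground_truth(residues = 1:3, s2 = 1, tau_e_ps = 0)
  r <- gen_modelfree_rates(rigid, fields = 800)
  direct <- predict_rates(1, 8.7, 0, 800)
  expect_equal(r$r1, rep(direct$r1, 3))
  expect_equal(r$r2, rep(direct$r2, 3))
  expect_equal(r$noe, rep(direct$noe, 3))

  slow <- gen_modelfree_rates(ground_truth(residues = 1, tau_c_ns = 8.7),
                              fields = 800)
  fast <- gen_modelfree_rates(ground_truth(residues = 1, tau_c_ns = 8.4),
                              fields = 800)
  expect_gt(slow$r2, fast$r2)
  expect_error(gen_modelfree_rates(ground_truth(s2 = 2)), "S2")
})
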