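test_that("cumulative shift differences: identities, arithmetic and symmetry", {
  tab <- data.frame(residue = 1:4, h = c(8.0, 8.1, 8.2, 8.3),
                    n = c(120, 121, 122, 123), ca = c(55, 56, 57, 58))
  expect_equal(delta_omega_cum(tab, tab)$dw_cum, rep(0, 4))

  # single nucleus with dw = std -> exactly 1
  one <- data.frame(residue = 1, h = 8.0)
  one_b <- data.frame(residue = 1, h = 8.0 + bmrb_shift_sd[["h"]])
  expect_equal(delta_omega_cum(one, one_b)$dw_cum, 1)

  # two nuclei with dw/std = 0.6 and 0.8 -> sqrt((0.36+0.64)/2)
  two <- data.frame(residue = 1, h = 8.0, n = 120)
  two_b <- data.frame(residue = 1, h = 8.0 + 0.6 * bmrb_shift_sd[["h"]],
                      n = 120 + 0.8 * bmrb_shift_sd[["n"]])
  expect_equal(delta_omega_cum(two, two_b)$dw_cum, sqrt(0.5), tolerance = 1e-12)

  # symmetric in its two arguments
  a <- data.frame(residue = 1:3, h = c(8, 8.2, 8.4), n = c(120, 118, 116))
  b <- data.frame(residue = 1:3, h = c(8.1, 8.2, 8.3), n = c(121, 117, 119))
  expect_equal(delta_omega_cum(a, b)$dw_cum, delta_omega_cum(b, a)$dw_cum)

  # adding a nucleus with zero difference changes the value only through N
  with_ca <- cbind(a, ca = c(55, 56, 57))
  with_ca_b <- cbind(b, ca = c(55, 56, 57))
  d2 <- delta_omega_cum(a, b)$dw_cum
  d3 <- delta_omega_cum(with_ca, with_ca_b)$dw_cum
  expect_equal(d3, d2 * sqrt(2 / 3), tolerance = 1e-12)

  # residue with no shared nucleus is dropped with a message
  a2 <- data.frame(residue = 1:2, h = c(8, NA), n = c(120, NA))
  expect_message(out <- delta_omega_cum(a2, b[1:2, ]), "dropped")
  expect_equal(out$residue, 1)
})

test_that("combined amide CSP", {
  expect_equal(combined_csp(0, 0), 0)
  expect_equal(combined_csp(-0.2, 0), 0.2)
  expect_equal(combined_csp(0.1, 0.65), sqrt(0.01 + (0.154 * 0.65)^2))
})

test_that("binding isotherm limits and Kd fitting round-trips", {
  expect_equal(binding_fraction(0, 2e-4, 7e-6), 0)
  # weak binding: converges to the hyperbolic isotherm
  L <- c(1, 5, 20, 100) * 1e-6
  f_exact <- binding_fraction(L, 1e-9, 50e-6)
  expect_equal(f_exact, L / (L + 50e-6), tolerance = 0.01)

  for (kd in c(7e-6, 100e-6)) {
    tr <- ground_truth(residues = 1:2, kd = kd)
    tit <- gen_titration(tr)
    kf <- suppressWarnings(fit_kd(tit, p_total = 2e-4))
    expect_lt(max(abs(kf$residues$kd - kd) / kd), 0.1)
    expect_equal(kf$residues$ddmax, rep(0.15, 2), tolerance = 1e-3)
  }

  # a truncated titration (far from saturation) is flagged
  weak <- ground_truth(residues = 1, kd = 5e-3)
  tit_w <- gen_titration(weak)
  expect_warning(fw <- fit_kd(tit_w, 2e-4), "saturation")
  expect_true(fw$residues$saturation_flag)

  # shared global Kd
  kg <- fit_kd(gen_titration(ground_truth(kd = 19e-6)), 2e-4, global = TRUE)
  expect_equal(kg$kd_global, 19e-6, tolerance = 1e-6)
  expect_error(fit_kd(data.frame(residue = 1, ligand = c(0, 1e-5),
                                 csp = c(0, 0.1)), 2e-4), "4 titration")
})

test_that("dispersion-versus-binding shift correlation", {
  x <- c(0.2, 0.5, 0.8, 1.1)
  out <- correlate_dw(x, 2 * x)
  expect_equal(out$r, 1)
  expect_equal(out$slope, 2)
  # anticorrelated magnitudes
  expect_equal(correlate_dw(x, max(x) + 0.1 - x)$r, -1, tolerance = 1e-12)
  # matching by residue names
  out2 <- correlate_dw(c(a = 1, b = 2, c = 3, zzz = 9),
                       c(c = 6, a = 2, b = 4))
  expect_equal(out2$n, 3)
  expect_equal(out2$r, 1)
  expect_error(correlate_dw(c(1, 2), c(2, 4)), "3")
  expect_error(correlate_dw(c(1, 1, 1), c(1, 2, 3)), "variance")

  # independent vectors: |r| rarely large (null behaviour)
  set.seed(77)
  rs <- replicate(300, {
    correlate_dw(runif(15, 0, 1), runif(15, 0, 1))$r
  })
  expect_lt(abs(mean(rs)), 0.1)
  expect_gt(mean(abs(rs) < 0.6), 0.95)
})
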