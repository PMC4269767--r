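flat_plane <- function(value, np = c(32, 24), meta = list()) {
  gridded_plane(matrix(value, np[1], np[2]),
                seq(10, 6, length.out = np[1]),
                seq(130, 105, length.out = np[2]), meta = meta)
}

test_that("box summation returns exact sums on constructed planes", {
  p <- flat_plane(3)
  expect_equal(box_sum_volume(p, 8, 118, box = 5), 25 * 3)

  z <- matrix(0, 32, 24)
  z[16, 12] <- 7
  p1 <- gridded_plane(z, p$h_ppm, p$n_ppm)
  expect_equal(box_sum_volume(p1, p$h_ppm[16], p$n_ppm[12], box = 5), 7)

  # peak one point from the edge: explicit error, no silent truncation
  z2 <- matrix(0, 32, 24)
  z2[2, 12] <- 5
  p2 <- gridded_plane(z2, p$h_ppm, p$n_ppm)
  expect_error(box_sum_volume(p2, p$h_ppm[2], p$n_ppm[12], box = 5), "edge")
})

test_that("volumes are linear in intensity and translation-consistent", {
  pk <- data.frame(residue = 1, h_ppm = 8.0, n_ppm = 117)
  p <- gen_plane(pk, h_range = c(10, 6), n_range = c(130, 105),
                 np = c(64, 48))
  v <- box_sum_volume(p, 8.0, 117)
  p_scaled <- gridded_plane(3.5 * p$intensity, p$h_ppm, p$n_ppm)
  expect_equal(box_sum_volume(p_scaled, 8.0, 117), 3.5 * v)

  # shift plane and peak by the same whole-point offset
  dh <- p$h_ppm[2] - p$h_ppm[1]
  z_shift <- rbind(p$intensity[-1, ], 0)
  p_shift <- gridded_plane(z_shift, p$h_ppm, p$n_ppm)
  expect_equal(box_sum_volume(p_shift, 8.0 - dh, 117), v, tolerance = 1e-9)
})

test_that("quantify_series recovers synthetic decays and flags coverage gaps", {
  pk <- data.frame(residue = c(10, 11), h_ppm = c(8.0, 9.2),
                   n_ppm = c(112, 124), amp = c(100, 80))
  ts <- c(0.01, 0.05, 0.1, 0.2)
  planes <- lapply(ts, function(t) {
    pk_t <- pk
    pk_t$amp <- pk$amp * exp(-2 * t)
    gen_plane(pk_t, np = c(128, 96), meta = list(kind = "delay_s", value = t))
  })
  series <- quantify_series(planes, pk)
  for (r in pk$residue) {
    s <- series[series$residue == r, ]
    rate <- -coef(lm(log(s$intensity) ~ s$x))[2]
    expect_equal(unname(rate), 2, tolerance = 0.01)
  }

  one <- quantify_series(planes[1], pk)
  expect_equal(nrow(one), 2)

  # residue outside grid coverage is excluded and reported
  pk_bad <- rbind(pk, data.frame(residue = 99, h_ppm = 10.49,
                                 n_ppm = 131.9, amp = 1))
  expect_message(out <- quantify_series(planes, pk_bad), "excluded")
  expect_equal(attr(out, "excluded"), 99)
  expect_false(99 %in% out$residue)

  # calibration mismatch between planes is an error
  other <- gen_plane(pk, h_range = c(11, 6), np = c(128, 96),
                     meta = list(kind = "delay_s", value = 0.3))
  expect_error(quantify_series(c(planes, list(other)), pk), "calibration")
})

test_that("plane and peak list text formats round-trip", {
  pk <- data.frame(residue = 1, h_ppm = 8.0, n_ppm = 117)
  p <- gen_plane(pk, np = c(32, 16), meta = list(kind = "nu_cpmg_hz",
                                                 value = 600))
  f <- tempfile(fileext = ".mat")
  write_plane(p, f)
  p2 <- read_plane(f)
  expect_equal(p2$intensity, p$intensity, tolerance = 1e-8)
  expect_equal(p2$h_ppm, p$h_ppm, tolerance = 1e-9)
  expect_equal(p2$meta$value, 600)

  fp <- tempfile(fileext = ".tsv")
  writeLines("residue\taa\th_ppm\tn_ppm\n5\tALA\t8.1\t120.5", fp)
  peaks <- read_peaks(fp)
  expect_equal(peaks$residue, 5)
  writeLines("residue\taa\th_ppm\tn_ppm\n5\tALA\t8.1\t120.5\n5\tGLY\t7.9\t110", fp)
  expect_error(read_peaks(fp), "unique")
})
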