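test_that("marginal moments follow the population conventions", {
  m <- marginal_moments(matrix(c(0, 1), 4, 4))
  expect_equal(unname(m), c(0.5, 0.25, 0, 1))   # two-point symmetric
  expect_equal(unname(marginal_moments(matrix(2.5, 5, 5))), c(2.5, 0, 0, 3))
  # lognormal: right-skewed, sign known in closed form
  x <- with_seed(5, exp(matrix(rnorm(64^2, sd = 0.5), 64)))
  expect_gt(marginal_moments(x)[["skewness"]], 0)
  expect_error(marginal_moments(c(1, NA)), "non-finite")
})

test_that("central autocorrelation matches the direct spatial-domain sum", {
  for (seed in 1:5) {
    m <- random_image(seed, 64)
    expect_lt(max(abs(central_autocorrelation(m, 7) -
                        direct_autocorrelation(m, 7))), 1e-10)
  }
  expect_error(central_autocorrelation(matrix(rnorm(16), 4), 4), "odd")
})

test_that("central autocorrelation: normalization, periodicity, null", {
  m <- random_image(9, 64)
  ac <- central_autocorrelation(m, 7)
  expect_equal(ac[4, 4], 1)
  # point symmetry about the center
  expect_lt(max(abs(ac - ac[7:1, 7:1])), 1e-8)
  # horizontally periodic map: unit correlation at lags that are multiples
  # of the period (period 4 fits twice inside the 9-wide window)
  per <- matrix(sin(2 * pi * (seq_len(64) - 1) / 4), 64, 64, byrow = TRUE)
  acp <- central_autocorrelation(per, 9)
  expect_equal(acp[5, 1], 1, tolerance = 1e-10)   # lag (0, -4)
  expect_equal(acp[5, 9], 1, tolerance = 1e-10)   # lag (0, +4)
  # white noise: off-center entries stay within +/- 4 / sqrt(N)
  off <- ac; off[4, 4] <- NA
  expect_lt(max(abs(off), na.rm = TRUE), 4 / sqrt(64^2))
  # degenerate map: delta at center
  acd <- central_autocorrelation(matrix(1, 16, 16), 5)
  expect_equal(acd, {d <- matrix(0, 5, 5); d[3, 3] <- 1; d})
})

test_that("phase doubling preserves magnitude and doubles phase", {
  z <- matrix(0 + 0i, 8, 8)
  expect_equal(phase_double_upsample(z), matrix(0 + 0i, 16, 16))
  # constant-phase map: phase doubled, magnitude kept
  c0 <- matrix(complex(modulus = 2, argument = 0.7), 8, 8)
  u <- phase_double_upsample(c0)
  expect_lt(max(abs(Mod(u) - 2)), 1e-6)
  expect_lt(max(abs(Arg(u) - 1.4)), 1e-6)
  # random map: |output| equals the modulus of an independent zero-pad
  # upsampling of the input (phase doubling never changes magnitude)
  b <- with_seed(3, matrix(complex(real = rnorm(64), imaginary = rnorm(64)), 8))
  up_oracle <- local({
    B <- texturality:::fftshift2(stats::fft(b))
    P <- texturality:::pad_center(B, 16)
    stats::fft(texturality:::ifftshift2(P), inverse = TRUE) / length(P) * 4
  })
  expect_lt(max(abs(Mod(phase_double_upsample(b)) - Mod(up_oracle))), 1e-6)
  expect_error(phase_double_upsample(b, 24), "twice")
})

test_that("cross-band correlation obeys its conventions", {
  m1 <- random_image(4, 16)
  expect_equal(cross_band_correlation(list(m1, -m1)),
               matrix(c(1, -1, -1, 1), 2), tolerance = 1e-12)
  # independent white noise: off-diagonals within +/- 4 / sqrt(N)
  maps <- lapply(5:8, random_image, n = 64)
  cc <- cross_band_correlation(maps)
  expect_lt(max(abs(cc - diag(4))), 4 / sqrt(64^2))
  # shifting every map by a full period of a periodic pattern changes nothing
  per <- lapply(c(0, pi / 3), function(ph)
    matrix(sin(2 * pi * (seq_len(64) - 1) / 8 + ph), 64, 64, byrow = TRUE))
  shifted <- lapply(per, function(m) m[, c(9:64, 1:8)])
  expect_lt(max(abs(cross_band_correlation(per, shifted) -
                      cross_band_correlation(per, per))), 1e-8)
  # zero-variance convention
  cz <- cross_band_correlation(list(m1, matrix(1, 16, 16)))
  expect_equal(cz[1, 2], 0)
  expect_equal(diag(cz), c(1, 1))
  expect_error(cross_band_correlation(list()), "empty")
})

test_that("full statistics are finite, shift-invariant and affine-stable", {
  ps <- noise_stats()$ps
  row <- ps_to_row(ps)
  expect_true(all(is.finite(row)))
  expect_equal(anyDuplicated(names(row)), 0L)
  # circular shift by multiples of 2^n_scales leaves every statistic alone
  x <- noise_stats()$image
  xs <- x[c(17:256, 1:16), c(241:256, 1:240)]
  expect_lt(max(abs(ps_to_row(compute_ps_statistics(xs)) - row)), 1e-8)
  # affine intensity change a*x + b: shapes invariant, variance scales a^2
  ps2 <- compute_ps_statistics(0.5 * x + 0.2)
  expect_equal(ps2$lowpass_skew, ps$lowpass_skew, tolerance = 1e-8)
  expect_equal(ps2$lowpass_kurt, ps$lowpass_kurt, tolerance = 1e-8)
  expect_equal(ps2$pixel_stats[["variance"]], 0.25 * ps$pixel_stats[["variance"]],
               tolerance = 1e-10)
  for (s in 1:4) {
    expect_lt(max(abs(ps2$cross_ori_mag[[s]] - ps$cross_ori_mag[[s]])), 1e-8)
    expect_lt(max(abs(ps2$cross_ori_real[[s]] - ps$cross_ori_real[[s]])), 1e-8)
    expect_lt(max(abs(ps2$raw_autocorr[[s]] - ps$raw_autocorr[[s]])), 1e-8)
  }
  for (s in 1:3) {
    expect_lt(max(abs(ps2$cross_scale_mag[[s]] - ps$cross_scale_mag[[s]])), 1e-8)
    expect_lt(max(abs(ps2$cross_scale_real[[s]] - ps$cross_scale_real[[s]])), 1e-8)
  }
})

test_that("statistic-set invariants hold on a non-trivial image", {
  ps <- noise_stats()$ps
  for (s in 1:5) {
    ac <- ps$raw_autocorr[[s]]
    expect_equal(ac[4, 4], 1)
    expect_lt(max(abs(ac - ac[7:1, 7:1])), 1e-8)
  }
  for (s in 1:4) {
    for (m in list(ps$cross_ori_mag[[s]], ps$cross_ori_real[[s]])) {
      expect_equal(m, t(m), tolerance = 1e-12)
      expect_equal(unname(diag(m)), rep(1, 4))
      expect_true(all(abs(m) <= 1 + 1e-12))
    }
  }
})

test_that("constant and near-Gaussian images hit the stated conventions", {
  psc <- compute_ps_statistics(matrix(0.5, 256, 256))
  expect_equal(unname(psc$pixel_stats[c("variance", "skewness", "kurtosis")]),
               c(0, 0, 3))
  expect_equal(psc$lowpass_skew, rep(0, 5))
  expect_equal(psc$lowpass_kurt, rep(3, 5))
  for (s in 1:4) expect_equal(psc$cross_ori_mag[[s]], diag(4))
  expect_true(all(is.finite(ps_to_row(psc))))
  # symmetric unimodal source with known mean / sd: moment recovery
  # (tolerances from the 100-seed Monte Carlo of the calibration criterion)
  x <- with_seed(55, matrix(0.5 + 0.1 * rnorm(256^2), 256))
  px <- compute_ps_statistics(x)$pixel_stats
  expect_equal(px[["mean"]], 0.5, tolerance = 0.01)
  expect_lt(abs(px[["skewness"]]), 0.05)
  expect_lt(abs(px[["kurtosis"]] - 3), 0.1)
})
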