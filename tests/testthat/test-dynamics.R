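test_that("temporal_acf is the biased autocovariance, matching direct lag sums", {
  # pure cosine over an integer number of cycles
  n <- 512; f <- 8 / n
  x <- cos(2 * pi * f * seq_len(n))
  a <- temporal_acf(x, frame_interval_s = 0.035)
  direct <- acv_direct(x)
  expect_lt(max(abs(a$acf - direct)), 1e-10)
  # the biased estimator tapers an integer-cycle cosine by (1 - lag/n), up to
  # the partial-cycle remainder of the doubled-frequency cross terms
  lags <- 0:63
  expect_lt(max(abs(a$acf[lags + 1] / a$acf[1] -
                      (1 - lags / n) * cos(2 * pi * f * lags))), 0.03)
  expect_equal(a$acf[1], mean((x - mean(x))^2))
  expect_equal(a$lags_s[2], 0.035)

  # a constant trace has an all-zero ACF, and short traces are rejected
  expect_true(all(temporal_acf(rep(3, 32))$acf == 0))
  expect_error(temporal_acf(c(1, 2, 3)), class = "ipws_domain_error")

  # random traces agree with the direct oracle too
  set.seed(1)
  y <- rnorm(100)
  expect_lt(max(abs(temporal_acf(y)$acf - acv_direct(y))), 1e-12)
})

test_that("correlation time is recovered from a process with exponential ACF", {
  t_c <- 0.5
  cube <- ar1_cube(t_c, n_frames = 2000, ny = 8, nx = 8, seed = 5)
  tc_hat <- vapply(1:8, function(i) {
    temporal_acf(cube$intensities[, i, i], 0.032)$t_c_s
  }, numeric(1))
  expect_rel_equal(mean(tc_hat), t_c, 0.10)
})

test_that("Sigma_t^2 is the per-pixel temporal variance", {
  ens <- scatterer_ensemble(50, 2e-4, fov_um = c(2, 2), mobile = FALSE,
                            seed = 7)
  meta <- acquisition_meta(550, 0.032, n_frames = 12, pixel_size_um = 0.25,
                           medium_ri = 1.46)
  static <- render_interference(ens, meta, 8, 8, noise = NULL, seed = 7)
  m <- compute_sigma_t2(static)
  expect_true(all(m$values == 0))

  # cosine trace over integer periods: variance = a^2 / 2
  n <- 128; a <- 0.004
  tr <- 0.02 + a * cos(2 * pi * 4 * seq_len(n) / n)
  cube <- temporal_cube(array(rep(tr, 4), c(n, 2, 2)),
                        acquisition_meta(550, 0.032, n_frames = n))
  m2 <- compute_sigma_t2(cube)
  expect_rel_equal(m2$values[1, 1], a^2 / 2, 1e-10)
})

test_that("reference subtraction removes the noise floor and clamps negatives", {
  samp <- noise_cube(2e-4, n_frames = 400, seed = 11)
  samp$is_reference <- FALSE
  ref <- noise_cube(2e-4, n_frames = 400, seed = 12)
  m <- compute_sigma_t2(samp, ref)
  # a pure-noise cube lands within 3 SE of zero after subtraction
  v_ref <- ipws:::pixel_variance(ref)
  se <- sd(v_ref) / sqrt(length(v_ref))
  expect_lt(abs(m$provenance$spatial_mean_unclamped), 3 * se)
  # roughly half the pixels clamp negative
  expect_gt(m$provenance$clamped_fraction, 0.2)
  expect_true(all(m$values[m$valid] >= 0))

  bad_ref <- noise_cube(2e-4, n_frames = 200, seed = 12)
  expect_error(compute_sigma_t2(samp, bad_ref), class = "ipws_format_error")
})

test_that("exposure attenuation follows the boxcar closed form", {
  expect_equal(exposure_attenuation(1), 2 * exp(-1) / 1 + 0, tolerance = 1e-12)
  expect_equal(exposure_attenuation(1), 0.73576, tolerance = 1e-4)
  expect_equal(exposure_attenuation(0.01), 1, tolerance = 0.01)
  expect_lt(abs(exposure_attenuation(1e-6) - 1), 1e-6)
  # large x: f -> 2/x
  expect_rel_equal(exposure_attenuation(50), 2 / 50 * (1 - 1 / 50), 1e-6)
  expect_equal(exposure_correction(1, t_c_s = 1, exposure_time_s = 1),
               1 / (2 * exp(-1)))
  expect_error(exposure_correction(1, t_c_s = -1, exposure_time_s = 0.03),
               class = "ipws_domain_error")
})

test_that("fractional moving mass is calibrated Sigma_t^2", {
  samp <- ar1_cube(0.1, n_frames = 300, seed = 13)
  ref <- noise_cube(1e-5, n_frames = 300, seed = 14)
  st <- compute_sigma_t2(samp, ref)
  mf <- fractional_moving_mass(st)
  expect_equal(mf$values, st$values)
  expect_equal(mf$what, "m_f")
  mf2 <- fractional_moving_mass(st, calibration_constant = 2.5)
  expect_equal(mf2$values, 2.5 * st$values)
  expect_error(fractional_moving_mass(st, calibration_constant = -1),
               class = "ipws_domain_error")
  expect_warning(fractional_moving_mass(compute_sigma_t2(samp)),
                 "reference")
})

test_that("the SNR filter keeps pixels strictly above sqrt(2) x background", {
  acf0 <- matrix(c(1, 1.9, 2, 1.4), 2, 2)
  mask <- snr_filter(acf0, background = 1)
  expect_identical(as.vector(mask), c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(attr(mask, "fraction_retained"), 0.5)
  expect_error(snr_filter(acf0, background = 0), class = "ipws_domain_error")

  # a signal-free cube is rejected almost everywhere against its reference
  samp <- noise_cube(2e-4, n_frames = 400, seed = 15)
  bg <- background_acf(noise_cube(2e-4, n_frames = 400, seed = 16))
  acv <- ipws:::cube_acv(samp)
  mask2 <- snr_filter(acv, bg)
  expect_lt(mean(mask2), 0.05)
})

test_that("estimate_D_mean recovers D from an ensemble with exact exponential ACF", {
  t_c <- 0.5
  meta <- acquisition_meta(550, 0.032, n_frames = 3000, pixel_size_um = 0.25,
                           medium_ri = 1.46)
  k <- meta$wavenumber_um
  cube <- ar1_cube(t_c, n_frames = 3000, ny = 8, nx = 8, seed = 17,
                   sd_signal = 1e-3, meta = meta)
  ref <- noise_cube(1e-5, n_frames = 3000, seed = 18)
  d <- estimate_D_mean(cube, ref)
  expect_true(d$valid)
  expect_equal(d$n_valid_px, 64)
  d_true <- 1 / (4 * k^2 * t_c)
  expect_equal(d_true, 1.797e-3, tolerance = 1e-3)
  expect_rel_equal(d$mean_D, d_true, 0.02)
})

test_that("a frozen cube fails the SNR filter and raises an estimation error", {
  frozen <- noise_cube(2e-4, n_frames = 300, seed = 19)
  frozen$is_reference <- FALSE
  ref <- noise_cube(2e-4, n_frames = 300, seed = 20)
  expect_error(estimate_D_mean(frozen, ref), class = "ipws_estimation_error")
})

test_that("slope lags are configurable and recorded", {
  cube <- ar1_cube(0.5, n_frames = 1500, ny = 8, nx = 8, seed = 21)
  ref <- noise_cube(1e-5, n_frames = 1500, seed = 22)
  d12 <- estimate_D_mean(cube, ref, slope_lags = c(1, 2))
  d01 <- estimate_D_mean(cube, ref, slope_lags = c(0, 1))
  expect_equal(d12$provenance$slope_lags, c(1L, 2L))
  # instantaneous samples of an exponential process: both conventions agree
  expect_rel_equal(d01$mean_D, d12$mean_D, 0.05)
})

test_that("estimate_D_map with sigma = 0 matches a per-pixel two-point evaluation", {
  cube <- ar1_cube(0.3, n_frames = 1200, ny = 6, nx = 6, seed = 23)
  ref <- noise_cube(1e-5, n_frames = 1200, ny = 6, nx = 6, seed = 24)
  bg <- background_acf(ref)
  dmap <- estimate_D_map(cube, bg, gaussian_sigma_px = 0)
  k <- cube$meta$wavenumber_um
  for (iy in 1:6) for (ix in 1:6) {
    a <- acv_direct(cube$intensities[, iy, ix]) - bg$acf
    an <- a / a[1]
    expected <- log(an[2] / an[3]) / 0.032 / (4 * k^2)
    expect_equal(dmap$values[iy, ix], expected, tolerance = 1e-8)
  }
})

test_that("a spatially uniform cube yields a near-uniform D map", {
  cube <- ar1_cube(0.2, n_frames = 2000, ny = 10, nx = 10, seed = 25)
  ref <- noise_cube(1e-5, n_frames = 2000, ny = 10, nx = 10, seed = 26)
  dmap <- estimate_D_map(cube, ref, gaussian_sigma_px = 2)
  v <- dmap$values[dmap$valid]
  expect_gt(length(v), 90)
  expect_lt(sd(v) / mean(v), 0.20)
})

test_that("a two-region cube with 4x different D separates in the map", {
  meta <- acquisition_meta(550, 0.032, n_frames = 2000, pixel_size_um = 0.25,
                           medium_ri = 1.46)
  slow <- ar1_cube(0.4, n_frames = 2000, ny = 8, nx = 4, seed = 27, meta = NULL)
  fast <- ar1_cube(0.1, n_frames = 2000, ny = 8, nx = 4, seed = 28, meta = NULL)
  arr <- array(0, c(2000, 8, 8))
  arr[, , 1:4] <- slow$intensities
  arr[, , 5:8] <- fast$intensities
  cube <- temporal_cube(arr, slow$meta)
  ref <- noise_cube(1e-5, n_frames = 2000, seed = 29)
  dmap <- estimate_D_map(cube, ref, gaussian_sigma_px = 1)
  med_slow <- median(dmap$values[, 1:4], na.rm = TRUE)
  med_fast <- median(dmap$values[, 5:8], na.rm = TRUE)
  expect_gt(med_fast / med_slow, 2)
})

test_that("the sensitivity range brackets D between exposure and acquisition limits", {
  k <- wavenumber(550, 1.46)
  sr <- sensitivity_range(0.032, 6.432, k)
  expect_equal(sr$D_max, 1 / (4 * k^2 * 0.032))
  expect_equal(sr$D_max, 2.81e-2, tolerance = 1e-2)
  expect_equal(sr$D_min, 1.40e-4, tolerance = 1e-2)
  expect_lt(sr$D_min, sr$D_max)
  # doubling the acquisition halves D_min
  sr2 <- sensitivity_range(0.032, 2 * 6.432, k)
  expect_equal(sr2$D_min, sr$D_min / 2)
  expect_error(sensitivity_range(1, 0.5, k))
})
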