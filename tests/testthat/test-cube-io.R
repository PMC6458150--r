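test_that("acquisition metadata validates physical invariants", {
  m <- acquisition_meta(550, exposure_time_s = 0.032, n_frames = 201,
                        pixel_size_um = 0.25, medium_ri = 1.46)
  expect_equal(m$acquisition_time_s, 6.432)
  expect_equal(m$wavenumber_um, 2 * pi * 1.46 / 0.55)
  expect_error(acquisition_meta(350, 0.032), class = "ipws_metadata_error")
  expect_error(acquisition_meta(550, exposure_time_s = 0.05,
                                frame_interval_s = 0.032),
               class = "ipws_metadata_error")
  expect_error(acquisition_meta(c(600, 500, 700), 0.035),
               class = "ipws_metadata_error")
})

test_that("cube constructors enforce shape and wavelength invariants", {
  m <- small_meta(10)
  expect_error(temporal_cube(array(0.1, c(5, 4, 4)), m),
               class = "ipws_format_error")  # n_frames mismatch
  arr <- array(0.1, c(10, 4, 4)); arr[3, 2, 2] <- NaN
  expect_error(temporal_cube(arr, m), class = "ipws_format_error")
  ms <- acquisition_meta(seq(500, 700, 2), 0.035)
  expect_s3_class(spectral_cube(array(0.1, c(101, 4, 4)), ms), "pws_cube")
  expect_error(spectral_cube(array(0.1, c(50, 4, 4)), ms),
               class = "ipws_format_error")
  expect_error(spectral_cube(array(0.1, c(2, 4, 4)),
                             acquisition_meta(c(500, 600), 0.035)),
               class = "ipws_metadata_error")
})

test_that("rds round-trip is bit-exact and tiff round-trip is quantization-exact", {
  cube <- random_cube(n_frames = 7, ny = 6, nx = 5, seed = 3)
  rds <- withr::local_tempfile(fileext = ".rds")
  write_cube(cube, rds)
  expect_identical(read_cube(rds), cube)

  tif <- withr::local_tempfile(fileext = ".tif")
  write_cube(cube, tif)
  back <- read_cube(tif, kind = "temporal")
  expect_equal(dim(back$intensities), dim(cube$intensities))
  expect_lt(max(abs(back$intensities - cube$intensities)) /
              max(cube$intensities), 2^-31)
  expect_equal(back$meta$wavelengths_nm, cube$meta$wavelengths_nm)
  expect_equal(back$meta$exposure_time_s, cube$meta$exposure_time_s)
  expect_equal(back$meta$pixel_size_um, cube$meta$pixel_size_um)

  # a second write-read cycle stays within one quantization step
  tif2 <- withr::local_tempfile(fileext = ".tif")
  write_cube(back, tif2)
  back2 <- read_cube(tif2, kind = "temporal")
  expect_lt(max(abs(back2$intensities - back$intensities)) /
              max(back$intensities), 2^-30)
})

test_that("spectral cubes round-trip with their wavelength axis", {
  ms <- acquisition_meta(seq(500, 700, 2), 0.035)
  set.seed(4)
  cube <- spectral_cube(array(runif(101 * 16, 0, 0.05), c(101, 4, 4)), ms)
  tif <- withr::local_tempfile(fileext = ".tif")
  write_cube(cube, tif)
  back <- read_cube(tif, kind = "spectral")
  expect_equal(back$meta$wavelengths_nm, seq(500, 700, 2))
  expect_equal(length(back$meta$wavelengths_nm), 101)
  expect_equal(diff(back$meta$wavelengths_nm)[1], 2)
})

test_that("reading rejects missing metadata and layout mismatches", {
  cube <- random_cube(n_frames = 5, ny = 4, nx = 4)
  tif <- withr::local_tempfile(fileext = ".tif")
  write_cube(cube, tif)

  # sidecar lacking exposure_time -> metadata error
  side <- yaml::read_yaml(paste0(tif, ".yaml"))
  side$exposure_time_s <- NULL
  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(side, bad)
  expect_error(read_cube(tif, kind = "temporal", meta_path = bad),
               class = "ipws_metadata_error")

  # sidecar declaring the wrong frame count -> never silently re-interpreted
  side <- yaml::read_yaml(paste0(tif, ".yaml"))
  side$n_frames <- 4
  bad2 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(side, bad2)
  expect_error(read_cube(tif, kind = "temporal", meta_path = bad2),
               class = "ipws_format_error")

  # declared kind must match the sidecar
  expect_error(read_cube(tif, kind = "spectral"), class = "ipws_format_error")

  # no sidecar at all
  orphan <- withr::local_tempfile(fileext = ".tif")
  file.copy(tif, orphan)
  expect_error(read_cube(orphan, kind = "temporal"),
               class = "ipws_metadata_error")
})

test_that("writing rejects non-finite and negative cubes", {
  cube <- random_cube(n_frames = 5)
  cube$intensities[2, 1, 1] <- -0.1
  expect_error(write_cube(cube, withr::local_tempfile(fileext = ".tif")),
               class = "ipws_format_error")
})

test_that("normalization implements (raw - dark) / (led * exposure)", {
  m <- small_meta(6)
  dark <- matrix(100, 4, 4)
  led <- matrix(5000, 4, 4)
  expos <- m$exposure_time_s

  raw_equal_dark <- temporal_cube(array(100, c(6, 4, 4)), m, normalized = FALSE)
  out <- normalize_cube(raw_equal_dark, dark, led)
  expect_true(all(out$intensities == 0))

  raw_ones <- temporal_cube(array(100 + 5000 * expos, c(6, 4, 4)), m,
                            normalized = FALSE)
  out1 <- normalize_cube(raw_ones, dark, led)
  expect_equal(max(abs(out1$intensities - 1)), 0, tolerance = 1e-12)

  expect_error(normalize_cube(raw_ones, dark, matrix(0, 4, 4)),
               class = "ipws_division_error")
  expect_error(normalize_cube(raw_ones, matrix(0, 3, 3), led),
               class = "ipws_format_error")
})

test_that("normalization is a warned pass-through without references, hence idempotent", {
  cube <- random_cube(n_frames = 8)
  expect_warning(out <- normalize_cube(cube), "dark/led")
  expect_equal(out$intensities, cube$intensities)
})

test_that("per-frame LED drift is removed by the estimated LED reference", {
  m <- small_meta(50)
  set.seed(5)
  truth <- array(rep(runif(16, 0.005, 0.02), each = 50), c(50, 4, 4))
  drift <- 1 + 0.5 * sin(seq_len(50) / 8)   # strong 2x-scale LED variation
  raw <- truth * drift
  cube <- temporal_cube(raw, m, normalized = FALSE)
  led <- estimate_led_reference(cube)
  out <- normalize_cube(cube, dark_frame = 0, led_reference = led,
                        exposure_time = 1)
  fm <- apply(out$intensities, 1, mean)
  expect_lt((max(fm) - min(fm)) / mean(fm), 0.01)
})
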