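# Shared fixture builders. Everything is generated in code under fixed seeds;
# no binary fixtures live in the repository.

small_meta <- function(n_frames = 10, ny = 4, nx = 4) {
  acquisition_meta(550, exposure_time_s = 0.032, n_frames = n_frames,
                   pixel_size_um = 0.25, medium_ri = 1.46)
}

random_cube <- function(n_frames = 10, ny = 16, nx = 16, seed = 1) {
  set.seed(seed)
  arr <- array(runif(n_frames * ny * nx, 0.001, 0.02), c(n_frames, ny, nx))
  temporal_cube(arr, small_meta(n_frames), normalized = TRUE)
}

# A cube whose pixel traces are AR(1) processes: the discrete process with
# exactly exponential autocorrelation exp(-tau/t_c), used as the analytic
# stand-in for diffusive interference fluctuations.
ar1_cube <- function(t_c_s, n_frames = 500, ny = 8, nx = 8,
                     frame_interval_s = 0.032, sd_signal = 1e-3,
                     baseline = 0.01, seed = 1, meta = NULL) {
  phi <- exp(-frame_interval_s / t_c_s)
  set.seed(seed)
  npx <- ny * nx
  x <- matrix(0, n_frames, npx)
  x[1, ] <- rnorm(npx, sd = sd_signal)
  innov_sd <- sd_signal * sqrt(1 - phi^2)
  for (t in 2:n_frames) {
    x[t, ] <- phi * x[t - 1, ] + rnorm(npx, sd = innov_sd)
  }
  arr <- array(x, c(n_frames, ny, nx)) + baseline
  if (is.null(meta)) {
    meta <- acquisition_meta(550, exposure_time_s = frame_interval_s,
                             frame_interval_s = frame_interval_s,
                             n_frames = n_frames, pixel_size_um = 0.25,
                             medium_ri = 1.46)
  }
  temporal_cube(arr, meta, normalized = TRUE)
}

# White-noise reference cube matching ar1_cube geometry.
noise_cube <- function(sd_noise, n_frames = 500, ny = 8, nx = 8,
                       frame_interval_s = 0.032, baseline = 0.01, seed = 2) {
  set.seed(seed)
  arr <- array(rnorm(n_frames * ny * nx, mean = baseline, sd = sd_noise),
               c(n_frames, ny, nx))
  meta <- acquisition_meta(550, exposure_time_s = frame_interval_s,
                           frame_interval_s = frame_interval_s,
                           n_frames = n_frames, pixel_size_um = 0.25,
                           medium_ri = 1.46)
  temporal_cube(arr, meta, normalized = TRUE, is_reference = TRUE)
}

# Direct (loop-based) biased autocovariance, the independent oracle for the
# FFT implementation.
acv_direct <- function(x) {
  x <- x - mean(x)
  n <- length(x)
  vapply(0:(n - 1), function(lag) {
    sum(x[seq_len(n - lag)] * x[seq_len(n - lag) + lag]) / n
  }, numeric(1))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
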