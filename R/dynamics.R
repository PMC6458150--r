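#' Temporal autocorrelation of a fluctuation trace
#'
#' Biased (1/N) autocovariance estimate per integer lag, computed via
#' zero-padded frequency-domain convolution. The biased estimator is the
#' standard choice in dynamic light scattering: it is stable at large lags
#' where the unbiased estimator blows up. `acf(0)` equals the population
#' variance of the trace. The temporal mean is removed first so the
#' fluctuations oscillate around zero.
#'
#' @param trace Numeric vector: reflectance at one pixel over time (>= 4
#'   frames).
#' @param frame_interval_s Seconds between samples.
#' @return A `pws_acf` list: `acf` (autocovariance per lag), `lags_s`
#'   (starting at 0, spaced by the frame interval), `normalized` (FALSE),
#'   `t_c_s` (correlation time from the geometric decay of lags 1-2, NA when
#'   undefined), and `truncation_lag` (first lag, in frames, with a
#'   non-positive value; NA if none).
#' @export
#' @examples
#' x <- as.vector(arima.sim(list(ar = 0.8), 512))
#' a <- temporal_acf(x, 0.035)
#' a$acf[1] / var(x)  # biased: (n-1)/n
temporal_acf <- function(trace, frame_interval_s = 1) {
  n <- length(trace)
  if (n < 4) {
    abort("Need at least 4 frames for an autocorrelation.",
          class = "ipws_domain_error")
  }
  acv <- acv_matrix(matrix(trace - mean(trace), ncol = 1))[, 1]
  new_pws_acf(acv, frame_interval_s)
}

new_pws_acf <- function(acv, frame_interval_s, normalized = FALSE) {
  n <- length(acv)
  nonpos <- which(acv <= 0)
  t_c <- NA_real_
  if (n >= 3 && acv[2] > 0 && acv[3] > 0 && acv[2] > acv[3]) {
    t_c <- frame_interval_s / log(acv[2] / acv[3])
  }
  structure(list(acf = acv,
                 lags_s = (seq_len(n) - 1) * frame_interval_s,
                 normalized = normalized,
                 t_c_s = t_c,
                 truncation_lag = if (length(nonpos)) nonpos[1] - 1L else NA_integer_),
            class = "pws_acf")
}

#' @export
print.pws_acf <- function(x, ...) {
  cat(sprintf("<pws_acf> %d lags, dt = %.4g s, acf(0) = %.4g%s, t_c = %.4g s\n",
              length(x$acf), x$lags_s[2] - x$lags_s[1], x$acf[1],
              if (x$normalized) " (normalized)" else "", x$t_c_s))
  invisible(x)
}

# Biased autocovariance of every column of X (frames x pixels), FFT-based.
acv_matrix <- function(x) {
  n <- nrow(x)
  nfft <- 2^ceiling(log2(2 * n))
  xf <- mvfft(rbind(x, matrix(0, nfft - n, ncol(x))))
  s <- Re(xf)^2 + Im(xf)^2
  a <- Re(mvfft(s, inverse = TRUE)) / nfft
  a[seq_len(n), , drop = FALSE] / n
}

# Per-pixel autocovariance stack of a temporal cube: array (n_lags, ny, nx).
cube_acv <- function(cube) {
  arr <- cube$intensities
  d <- dim(arr)
  x <- arr
  dim(x) <- c(d[1], d[2] * d[3])
  x <- sweep(x, 2, colMeans(x))
  a <- acv_matrix(x)
  dim(a) <- d
  a
}

#' Spatial-mean autocorrelation of a background / reference cube
#'
#' The empty-field reference cube's per-pixel autocovariances, averaged over
#' all pixels: the background ACF that the diffusion estimator subtracts from
#' each sample pixel's ACF, and whose lag-0 value anchors the SNR filter.
#'
#' @param reference_cube An empty-field temporal `pws_cube`.
#' @return A `pws_acf` (spatial-mean autocovariance per lag).
#' @export
background_acf <- function(reference_cube) {
  stopifnot(inherits(reference_cube, "pws_cube"),
            reference_cube$kind == "temporal")
  a <- cube_acv(reference_cube)
  d <- dim(a)
  dim(a) <- c(d[1], d[2] * d[3])
  new_pws_acf(rowMeans(a), reference_cube$meta$frame_interval_s)
}

#' SNR mask from lag-0 autocorrelation
#'
#' A pixel is kept only when its fluctuation power clears the background
#' noise floor: `acf(0) >= sqrt(2) * background_acf(0)`. A pixel whose
#' variance merely equals the background is rejected.
#'
#' @param acf_stack Per-pixel autocovariance array `(n_lags, ny, nx)` (e.g.
#'   from a temporal cube), or a `ny x nx` matrix of lag-0 values.
#' @param background A `pws_acf` from [background_acf()], or the scalar
#'   background lag-0 value.
#' @return Logical `ny x nx` mask; the retained fraction is reported via
#'   `attr(, "fraction_retained")`.
#' @export
snr_filter <- function(acf_stack, background) {
  acf0 <- if (is.matrix(acf_stack)) acf_stack else acf_stack[1, , ]
  bg0 <- if (inherits(background, "pws_acf")) background$acf[1] else background[1]
  if (!is.finite(bg0) || bg0 <= 0) {
    abort("Background acf(0) must be positive.", class = "ipws_domain_error")
  }
  mask <- acf0 >= sqrt(2) * bg0
  attr(mask, "fraction_retained") <- mean(mask)
  mask
}

#' Temporal fluctuation variance map (Sigma_t^2)
#'
#' Per pixel, the population variance of the mean-subtracted reflectance
#' trace over the acquisition. When a reference cube is supplied, the spatial
#' mean of the reference cube's `Sigma_t^2` (the instrument noise floor) is
#' subtracted from every pixel; negative results are clamped to zero and
#' flagged invalid.
#'
#' @param cube A normalized temporal `pws_cube`.
#' @param reference_cube Optional empty-field reference `pws_cube` with
#'   matching acquisition metadata.
#' @return A `pws_map` (`what = "sigma_t2"`) whose provenance records the
#'   subtracted noise level and the wavenumber convention.
#' @export
compute_sigma_t2 <- function(cube, reference_cube = NULL) {
  stopifnot(inherits(cube, "pws_cube"), cube$kind == "temporal")
  if (!cube$normalized) {
    warn("Cube is not flagged as normalized reflectance; Sigma_t^2 will be in raw units.")
  }
  v <- pixel_variance(cube)
  ref_level <- 0
  if (!is.null(reference_cube)) {
    assert_reference_compatible(cube, reference_cube)
    ref_level <- mean(pixel_variance(reference_cube))
    v <- v - ref_level
  }
  valid <- v >= 0
  # the unclamped spatial mean is the unbiased field average (clamping alone
  # would bias a pure-noise cube upward); kept in provenance for summaries
  unclamped_mean <- mean(v)
  v[!valid] <- 0
  map <- pws_map(pmax(v, 0), valid = valid, what = "sigma_t2",
                 provenance = list(
                   reference_subtracted = !is.null(reference_cube),
                   reference_level = ref_level,
                   clamped_fraction = mean(!valid),
                   spatial_mean_unclamped = unclamped_mean,
                   k_convention = cube$meta$k_convention))
  map
}

pixel_variance <- function(cube) {
  arr <- cube$intensities
  d <- dim(arr)
  x <- arr
  dim(x) <- c(d[1], d[2] * d[3])
  v <- colMeans(x^2) - colMeans(x)^2
  matrix(pmax(v, 0), d[2], d[3])
}

assert_reference_compatible <- function(cube, reference_cube) {
  m <- cube$meta; r <- reference_cube$meta
  same <- isTRUE(all.equal(m$exposure_time_s, r$exposure_time_s)) &&
    isTRUE(all.equal(m$frame_interval_s, r$frame_interval_s)) &&
    m$n_frames == r$n_frames &&
    isTRUE(all.equal(m$wavelengths_nm, r$wavelengths_nm))
  if (!same) {
    abort("Reference cube metadata does not match the sample cube.",
          class = "ipws_format_error")
  }
  assert_same_geometry(cube, reference_cube)
}

#' Finite-exposure attenuation correction for Sigma_t^2
#'
#' A camera that integrates intensity over an exposure window `E` attenuates
#' the measured variance of a fluctuation with exponential autocorrelation
#' (correlation time `t_c`) by the boxcar factor
#' \deqn{f(x) = 2 x^{-2} (x - 1 + e^{-x}), \quad x = E / t_c,}
#' which tends to 1 as `x -> 0` and to `2/x` for fast processes. This divides
#' the measured variance by `f(x)` to recover the unattenuated value, which
#' is how measured `Sigma_t` is put on the same footing as theory in phantom
#' validation.
#'
#' @param sigma_t2 A `pws_map` from [compute_sigma_t2()], or a numeric
#'   vector of variances.
#' @param t_c_s Correlation time, seconds (> 0).
#' @param exposure_time_s Exposure per frame, seconds.
#' @return Corrected map or vector; maps record the correction factor in
#'   provenance.
#' @export
#' @examples
#' exposure_attenuation(1)      # 2/e at x = 1
#' exposure_correction(1, t_c_s = 1, exposure_time_s = 1)  # = exp(1)/2
exposure_correction <- function(sigma_t2, t_c_s, exposure_time_s) {
  if (any(t_c_s <= 0)) {
    abort("`t_c_s` must be positive.", class = "ipws_domain_error")
  }
  stopifnot(exposure_time_s > 0)
  f <- exposure_attenuation(exposure_time_s / t_c_s)
  if (inherits(sigma_t2, "pws_map")) {
    out <- sigma_t2
    out$values <- out$values / f
    out$provenance <- c(out$provenance,
                        list(exposure_correction = list(
                          t_c_s = t_c_s, exposure_time_s = exposure_time_s,
                          attenuation = f)))
    out
  } else {
    sigma_t2 / f
  }
}

#' @rdname exposure_correction
#' @param x Ratio exposure_time / t_c.
#' @export
exposure_attenuation <- function(x) {
  ifelse(x < 1e-4,
         1 - x / 3 + x^2 / 12,
         2 * (x - 1 + exp(-x)) / x^2)
}

#' Fractional moving mass map
#'
#' The fractional moving mass `m_f = m_c * Phi` -- the mass of the typical
#' moving macromolecular cluster times the volume fraction of mobile mass --
#' is proportional to the reference-subtracted fluctuation variance
#' `Sigma_t^2`. The proportionality constant depends on instrument details,
#' so by default `m_f` is reported in normalized units
#' (`calibration_constant = 1`) and the constant is recorded in provenance.
#'
#' @param sigma_t2_map A `pws_map` from [compute_sigma_t2()] (reference
#'   subtraction recommended).
#' @param calibration_constant Non-negative multiplier mapping variance to
#'   mass units.
#' @return A `pws_map` (`what = "m_f"`).
#' @export
fractional_moving_mass <- function(sigma_t2_map, calibration_constant = 1) {
  stopifnot(inherits(sigma_t2_map, "pws_map"))
  if (calibration_constant < 0) {
    abort("`calibration_constant` must be non-negative.",
          class = "ipws_domain_error")
  }
  if (!isTRUE(sigma_t2_map$provenance$reference_subtracted)) {
    warn("Sigma_t^2 map was computed without reference subtraction; m_f will include instrument noise.")
  }
  out <- sigma_t2_map
  out$what <- "m_f"
  out$values <- out$values * calibration_constant
  out$provenance <- c(out$provenance,
                      list(calibration_constant = calibration_constant))
  out
}

# Shared core of the whole-field diffusion estimator: from an autocovariance
# matrix (lags x pixels) plus a background ACF, apply the SNR mask, subtract
# the background ACF, average the ACFs across valid pixels (amplitude
# weighted), normalize the mean ACF to 1 at lag 0, truncate it at its first
# non-positive value, and return its natural log. Averaging before the log
# keeps dim pixels from injecting log-scale noise bias.
mean_log_acf <- function(acv, bg, valid) {
  a <- acv[, valid, drop = FALSE] - bg
  ok0 <- a[1, ] > 0
  a <- a[, ok0, drop = FALSE]
  if (ncol(a) == 0) return(NULL)
  m <- rowMeans(a)
  m <- m / m[1]
  nonpos <- which(m <= 0)
  keep <- if (length(nonpos)) seq_len(nonpos[1] - 1L) else seq_along(m)
  list(mean_ln = log(m[keep]),
       n_lags = length(keep),
       n_valid = ncol(a))
}

#' Whole-field mean diffusion coefficient (temporal ACF method)
#'
#' Implements the complete diffusion analysis on a temporal cube:
#' mean-subtraction per pixel, per-pixel biased autocovariance, SNR filtering
#' against the background noise floor, subtraction of the mean background
#' ACF, averaging of the ACFs across valid pixels, normalization of the mean
#' ACF to 1 at lag zero, truncation at its first non-positive value (keeping
#' the lag spacing uniform for the logarithm), a two-point slope of the log
#' of the mean ACF, and finally
#' \deqn{D = -\mathrm{decay} / (4 k^2)}
#' with `k` the medium wavenumber from the cube metadata.
#'
#' The two slope points default to lags 1 and 2 (`slope_lags = c(1, 2)`).
#' Over lags >= 1 the autocovariance of an exposure-integrated exponential
#' process is exactly geometric with the true rate, whereas the lag-0 point
#' is both distorted by finite-exposure integration and contaminated by white
#' detection noise; `slope_lags = c(0, 1)` is available for comparison. The
#' cross-pixel average is taken on the ACFs themselves (amplitude-weighted)
#' before the logarithm, so dim pixels do not inject log-scale noise bias.
#' See the methods vignette for the full argument.
#'
#' No spatial filter is applied on this whole-field path (the per-pixel map
#' variant smooths the ACF stack instead, see [estimate_D_map()]).
#'
#' @param cube Normalized temporal `pws_cube`.
#' @param background A `pws_acf` from [background_acf()], or a reference
#'   `pws_cube` (converted internally), from a region without cells/spheres.
#' @param slope_lags Integer length-2: the two lags (in frames) of the mean
#'   log-ACF between which the decay slope is taken.
#' @return A `pws_d_estimate`: `mean_D` (um^2/s), `decay` (1/s), `valid`
#'   (FALSE when the slope is non-negative), `n_valid_px`, `mean_ln_acf`
#'   (tibble: `lag_s`, `mean_ln`), and provenance.
#' @export
estimate_D_mean <- function(cube, background, slope_lags = c(1L, 2L)) {
  stopifnot(inherits(cube, "pws_cube"), cube$kind == "temporal")
  bg <- as_background_acf(background, cube)
  slope_lags <- sort(as.integer(slope_lags))
  stopifnot(length(slope_lags) == 2, slope_lags[1] >= 0,
            slope_lags[2] > slope_lags[1],
            slope_lags[2] < cube$meta$n_frames)
  acv <- cube_acv(cube)
  d <- dim(acv)
  dim(acv) <- c(d[1], d[2] * d[3])
  mask <- snr_filter(matrix(acv[1, ], d[2], d[3]), bg)
  if (!any(mask)) {
    abort("No pixel passes the SNR filter; cannot estimate D.",
          class = "ipws_estimation_error")
  }
  ml <- mean_log_acf(acv, bg$acf, as.vector(mask))
  if (is.null(ml)) {
    abort("No pixel has positive background-subtracted variance.",
          class = "ipws_estimation_error")
  }
  finish_d_estimate(ml, cube$meta, slope_lags,
                    fraction_retained = attr(mask, "fraction_retained"))
}

as_background_acf <- function(background, cube) {
  if (inherits(background, "pws_cube")) {
    assert_reference_compatible(cube, background)
    background <- background_acf(background)
  }
  stopifnot(inherits(background, "pws_acf"))
  background
}

finish_d_estimate <- function(ml, meta, slope_lags, fraction_retained = NA) {
  dt <- meta$frame_interval_s
  k <- meta$wavenumber_um
  l1 <- slope_lags[1]; l2 <- slope_lags[2]
  curve <- tibble::tibble(lag_s = (seq_along(ml$mean_ln) - 1) * dt,
                          mean_ln = ml$mean_ln)
  y1 <- if (l1 == 0) 0 else ml$mean_ln[l1 + 1]
  y2 <- if (l2 + 1 <= length(ml$mean_ln)) ml$mean_ln[l2 + 1] else NA_real_
  if (is.na(y1) || is.na(y2)) {
    y1 <- 0; y2 <- NA_real_  # slope undefined: truncated before slope lags
  }
  decay <- (y2 - y1) / ((l2 - l1) * dt)
  mean_d <- -decay / (4 * k^2)
  structure(list(
    mean_D = mean_d,
    decay = decay,
    valid = is.finite(mean_d) && mean_d > 0,
    n_valid_px = ml$n_valid,
    mean_ln_acf = curve,
    provenance = list(k_um = k, k_convention = meta$k_convention,
                      slope_lags = slope_lags,
                      snr_fraction_retained = fraction_retained,
                      exposure_correction = FALSE)),
    class = "pws_d_estimate")
}

#' @export
print.pws_d_estimate <- function(x, ...) {
  cat(sprintf("<pws_d_estimate> D = %.4g um^2/s (%s), %d pixels, decay %.4g 1/s\n",
              x$mean_D, if (x$valid) "valid" else "INVALID", x$n_valid_px,
              x$decay))
  invisible(x)
}

#' @method glance pws_d_estimate
#' @export
glance.pws_d_estimate <- function(x, ...) {
  tibble::tibble(mean_D = x$mean_D, decay = x$decay, valid = x$valid,
                 n_valid_px = x$n_valid_px,
                 k_um = x$provenance$k_um,
                 snr_fraction_retained = x$provenance$snr_fraction_retained)
}

#' Per-pixel diffusion coefficient map
#'
#' The map variant of [estimate_D_mean()]: because a single pixel's ACF is
#' noisy, the ACF stack is smoothed spatially with a Gaussian filter
#' (`gaussian_sigma_px`, default 2) at each lag before per-pixel
#' normalization, truncation and the two-point slope. `gaussian_sigma_px = 0`
#' reproduces the unsmoothed per-pixel path exactly. Pixels failing the SNR
#' filter, with non-positive background-subtracted variance, or yielding a
#' non-positive D are masked.
#'
#' @inheritParams estimate_D_mean
#' @param gaussian_sigma_px Gaussian sigma of the per-lag spatial filter, in
#'   pixels.
#' @return A `pws_map` (`what = "D"`, um^2/s).
#' @export
estimate_D_map <- function(cube, background, gaussian_sigma_px = 2,
                           slope_lags = c(1L, 2L)) {
  stopifnot(inherits(cube, "pws_cube"), cube$kind == "temporal")
  bg <- as_background_acf(background, cube)
  slope_lags <- sort(as.integer(slope_lags))
  l2 <- slope_lags[2]
  acv <- cube_acv(cube)
  d <- dim(acv)
  mask <- snr_filter(acv, bg)
  if (gaussian_sigma_px > 0) {
    for (l in seq_len(l2 + 1)) {
      acv[l, , ] <- gaussian_blur(acv[l, , ], gaussian_sigma_px)
    }
  }
  a <- acv[seq_len(l2 + 1), , ]
  dim(a) <- c(l2 + 1, d[2] * d[3])
  a <- a - bg$acf[seq_len(l2 + 1)]
  ok <- as.vector(mask) & a[1, ] > 0
  an <- sweep(a, 2, a[1, ], "/")
  alive <- apply(an > 0, 2, cumprod) == 1
  ok <- ok & alive[l2 + 1, ] & (slope_lags[1] == 0 | alive[slope_lags[1] + 1, ])
  dt <- cube$meta$frame_interval_s
  y1 <- if (slope_lags[1] == 0) 0 else log(an[slope_lags[1] + 1, ])
  y2 <- suppressWarnings(log(an[l2 + 1, ]))
  decay <- (y2 - y1) / ((l2 - slope_lags[1]) * dt)
  k <- cube$meta$wavenumber_um
  dmap <- -decay / (4 * k^2)
  ok <- ok & is.finite(dmap) & dmap > 0
  pws_map(matrix(dmap, d[2], d[3]), valid = matrix(ok, d[2], d[3]),
          what = "D",
          provenance = list(k_um = k,
                            k_convention = cube$meta$k_convention,
                            gaussian_sigma_px = gaussian_sigma_px,
                            slope_lags = slope_lags,
                            snr_fraction_retained = attr(mask, "fraction_retained")))
}

# Separable Gaussian blur with edge renormalization (kernel radius 3 sigma).
gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  kern <- exp(-((-r):r)^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  blur1 <- function(m) {
    # convolve the columns of m with kern, renormalizing at the edges
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    wsum <- numeric(n)
    for (i in seq_along(kern)) {
      off <- i - r - 1L
      src <- seq_len(n) + off
      okr <- src >= 1 & src <= n
      out[okr, ] <- out[okr, ] + kern[i] * m[src[okr], , drop = FALSE]
      wsum[okr] <- wsum[okr] + kern[i]
    }
    out / wsum
  }
  t(blur1(t(blur1(mat))))
}

#' Diffusion-coefficient sensitivity range of an acquisition
#'
#' The temporal method resolves a process only if its correlation time fits
#' inside the acquisition: processes faster than the exposure are averaged
#' away within one frame, and processes slower than the total acquisition
#' never decorrelate. Under the default convention `t_c` in
#' `[exposure_time, acquisition_time]` and `D = 1/(4 k^2 t_c)`:
#' `D_max = 1/(4 k^2 exposure)`, `D_min = 1/(4 k^2 acquisition)`.
#'
#' @param exposure_time_s Exposure per frame, s.
#' @param acquisition_time_s Total acquisition, s (must exceed the exposure).
#' @param k_um Wavenumber, 1/um.
#' @param convention Convention string recorded in the output.
#' @return A tibble with `D_min`, `D_max` (um^2/s) and `convention`.
#' @export
sensitivity_range <- function(exposure_time_s, acquisition_time_s, k_um,
                              convention = "t_c within [exposure, acquisition]") {
  stopifnot(exposure_time_s > 0, acquisition_time_s > exposure_time_s,
            k_um > 0)
  tibble::tibble(
    D_min = 1 / (4 * k_um^2 * acquisition_time_s),
    D_max = 1 / (4 * k_um^2 * exposure_time_s),
    convention = convention
  )
}
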