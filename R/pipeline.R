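# Step-1 LED normalization: divide each frame by its self-referenced LED
# intensity (see estimate_led_reference); dark and exposure are identity for
# simulator cubes already in reflectance units.
led_normalize <- function(cube) {
  suppressWarnings(normalize_cube(cube, dark_frame = 0,
                                  led_reference = estimate_led_reference(cube),
                                  exposure_time = 1))
}

#' End-to-end phantom validation run
#'
#' Simulates nanosphere-phantom suites, runs the full dynamics analysis on
#' every cube, and compares the recovered quantities with theory: the
#' diffusion coefficient against the Stokes-Einstein prediction, and the
#' exposure-corrected fluctuation amplitude `Sigma_t` against the analytic
#' forward-model value. This is the package's self-validation: with the
#' simulator providing ground truth, agreement demonstrates that the
#' estimator chain (normalization, ACF, SNR filtering, background
#' subtraction, slope, exposure correction) is internally consistent.
#'
#' Exposure correction is applied to the `Sigma_t` comparison (using the
#' theoretical correlation time of each condition) but *not* to the
#' diffusion estimates: variance lost to exposure integration can be divided
#' back out, while the ACF decay over lags >= 1 needs no such correction.
#' Diffusion accuracy is summarised over the dilute (0.1%) arm only; fast
#' 0.3%/70% conditions fall outside the sensitivity range of the phantom
#' acquisition and are tracked for the `Sigma_t` comparison alone, mirroring
#' how such suites are reported.
#'
#' @param conditions Condition grid, see [phantom_conditions()]. Conditions
#'   with `volume_fraction = 0` are excluded from regressions (with a
#'   message) since they carry no signal.
#' @param n_seeds Replicate cubes per condition.
#' @param seed Master seed; replicate and condition seeds derive from it.
#' @param ny,nx Cube size in pixels.
#' @param noise Detection [noise_model()] shared by samples and reference.
#' @param d_accuracy_phi Volume fraction(s) whose conditions enter the
#'   diffusion-accuracy summary.
#' @param ... Passed to [make_phantom_suite()] (e.g. `depth_um`,
#'   `amplitude_scale`).
#' @return A `pws_validation` object; see [tidy.pws_validation()] and
#'   [glance.pws_validation()].
#' @export
run_phantom_validation <- function(conditions = phantom_conditions(include_03pct = TRUE),
                                   n_seeds = 5, seed = 1L,
                                   ny = 32, nx = 32,
                                   noise = noise_model(),
                                   d_accuracy_phi = 0.001, ...) {
  keep <- conditions$volume_fraction > 0
  if (any(!keep)) {
    inform(sprintf(
      "Excluding %d zero-volume-fraction condition(s) from regression (no signal).",
      sum(!keep)))
    conditions <- conditions[keep, ]
  }
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_seeds)
  rows <- vector("list", n_seeds)
  for (r in seq_len(n_seeds)) {
    suite <- make_phantom_suite(conditions, seed = rep_seeds[r],
                                ny = ny, nx = nx, noise = noise, ...)
    reference <- led_normalize(suite$reference)
    bg <- background_acf(reference)
    res <- purrr::map_dfr(seq_along(suite$cubes), function(i) {
      cube <- led_normalize(suite$cubes[[i]])
      man <- suite$manifest[i, ]
      d_est <- tryCatch(estimate_D_mean(cube, bg),
                        ipws_estimation_error = function(e) NULL)
      st <- compute_sigma_t2(cube, reference)
      st_raw <- st$provenance$spatial_mean_unclamped
      st_corr <- exposure_correction(st_raw, t_c_s = man$t_c_s,
                                     exposure_time_s = cube$meta$exposure_time_s)
      tibble::tibble(
        replicate = r, seed = rep_seeds[r],
        radius_nm = man$radius_nm, volume_fraction = man$volume_fraction,
        glycerol_pct = man$glycerol_pct,
        true_D = man$true_D,
        D_hat = if (is.null(d_est)) NA_real_ else d_est$mean_D,
        d_valid = !is.null(d_est) && d_est$valid,
        n_valid_px = if (is.null(d_est)) 0L else d_est$n_valid_px,
        sigma_t2_raw = st_raw,
        sigma_t2_corrected = st_corr,
        sigma_t2_theory = man$sigma_t2_analytic,
        t_c_s = man$t_c_s
      )
    })
    rows[[r]] <- res
  }
  out <- structure(
    list(results = dplyr::bind_rows(rows),
         d_accuracy_phi = d_accuracy_phi,
         manifest = list(seed = seed, n_seeds = n_seeds, ny = ny, nx = nx,
                         conditions = conditions,
                         noise = unclass(noise))),
    class = "pws_validation")
  out
}

#' @export
print.pws_validation <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<pws_validation> %d cubes (%d conditions x %d seeds)\n",
              nrow(x$results), nrow(x$manifest$conditions),
              x$manifest$n_seeds))
  cat(sprintf("  D:       R^2 = %.4f, mean |%%err| = %.2f%% (phi = %s)\n",
              g$r2_D, g$mean_abs_pct_err_D,
              paste(x$d_accuracy_phi, collapse = ", ")))
  cat(sprintf("  Sigma_t: R^2 = %.4f, mean |%%err| = %.2f%%\n",
              g$r2_sigma_t, g$mean_abs_pct_err_sigma_t))
  invisible(x)
}

#' Per-cube phantom validation results
#'
#' @param x A `pws_validation`.
#' @param ... Unused.
#' @return Tibble with one row per simulated cube: condition, ground truth,
#'   recovered D, raw/corrected/theoretical `Sigma_t^2`.
#' @method tidy pws_validation
#' @export
tidy.pws_validation <- function(x, ...) {
  x$results
}

#' Summary statistics of a phantom validation run
#'
#' @param x A `pws_validation`.
#' @param ... Unused.
#' @return One-row tibble: `r2_D` and `mean_abs_pct_err_D` (recovered vs
#'   Stokes-Einstein D over the dilute arm), `r2_sigma_t` and
#'   `mean_abs_pct_err_sigma_t` (exposure-corrected `Sigma_t` vs the analytic
#'   forward-model value over all conditions), and cube counts.
#' @method glance pws_validation
#' @export
glance.pws_validation <- function(x, ...) {
  res <- x$results
  dsub <- dplyr::filter(res, .data$volume_fraction %in% x$d_accuracy_phi,
                        is.finite(.data$D_hat))
  sig <- dplyr::filter(res, is.finite(.data$sigma_t2_corrected),
                       .data$sigma_t2_theory > 0)
  st_meas <- sqrt(pmax(sig$sigma_t2_corrected, 0))
  st_theo <- sqrt(sig$sigma_t2_theory)
  tibble::tibble(
    r2_D = r_squared(dsub$true_D, dsub$D_hat),
    mean_abs_pct_err_D = mean(abs(percent_change(dsub$true_D, dsub$D_hat))),
    r2_sigma_t = r_squared(st_theo, st_meas),
    mean_abs_pct_err_sigma_t = mean(abs(percent_change(st_theo, st_meas))),
    n_cubes = nrow(res),
    n_cubes_d = nrow(dsub)
  )
}

#' Timecourse analysis over paired cubes
#'
#' Runs the structural and dynamic summaries over an ordered series of
#' acquisitions of the same field: per timepoint, `Sigma_s` (when a spectral
#' cube is present) and the reference-subtracted `m_f` over an ROI, plus a
#' changepoint scan of the per-timepoint `m_f` trend that flags bursts of
#' motion across the series.
#'
#' @param records A tibble with columns `time_s` (strictly increasing),
#'   `temporal` (list of temporal `pws_cube`), optionally `spectral` (list
#'   of spectral cubes or NULL entries).
#' @param roi Logical matrix ROI (default: all pixels).
#' @param reference Optional reference `pws_cube`; if absent, noise
#'   subtraction is skipped with a warning and flagged in the output.
#' @param burst_penalty_factor Penalty for the trend changepoint scan.
#' @return A `pws_timecourse`: `summary` tibble (one row per timepoint:
#'   `time_s`, `m_f`, `sigma_s`), `burst` (one-row tibble with
#'   `burst_timepoint` index or NA), `reference_subtracted` flag.
#' @export
run_timecourse <- function(records, roi = NULL, reference = NULL,
                           burst_penalty_factor = 3) {
  stopifnot(is.data.frame(records),
            all(c("time_s", "temporal") %in% names(records)))
  if (is.unsorted(records$time_s, strictly = TRUE)) {
    abort("`time_s` must be strictly increasing; shuffled timecourses are rejected.",
          class = "ipws_format_error")
  }
  ref_ok <- !is.null(reference)
  if (!ref_ok) {
    warn("No reference cube supplied; noise subtraction skipped.")
  }
  n_t <- nrow(records)
  rows <- vector("list", n_t)
  for (i in seq_len(n_t)) {
    cube <- records$temporal[[i]]
    st <- compute_sigma_t2(cube, if (ref_ok) reference else NULL)
    mf <- fractional_moving_mass(st) |> suppressWarnings()
    sig_s <- NA_real_
    if ("spectral" %in% names(records) && !is.null(records$spectral[[i]])) {
      sm <- compute_sigma_s(records$spectral[[i]])
      msk <- roi %||% matrix(TRUE, nrow(sm$values), ncol(sm$values))
      sig_s <- roi_summary(sm, msk)$mean
    }
    msk <- roi %||% matrix(TRUE, nrow(mf$values), ncol(mf$values))
    rows[[i]] <- tibble::tibble(
      time_s = records$time_s[i],
      m_f = mean(mf$values[msk], na.rm = TRUE),
      sigma_s = sig_s)
  }
  summary <- dplyr::bind_rows(rows)
  burst_tp <- NA_integer_
  if (n_t >= 16) {
    cp <- detect_changepoint(summary$m_f, penalty_factor = burst_penalty_factor)
    burst_tp <- cp$onset_frame
  } else if (n_t >= 5) {
    # short series: flag the largest m_f excursion above the series median
    z <- (summary$m_f - median(summary$m_f)) /
      max(stats::mad(summary$m_f), .Machine$double.eps)
    if (max(z) > 5) burst_tp <- which.max(z)
  }
  structure(list(summary = summary,
                 burst = tibble::tibble(burst_timepoint = burst_tp),
                 reference_subtracted = ref_ok),
            class = "pws_timecourse")
}

#' @export
print.pws_timecourse <- function(x, ...) {
  cat(sprintf("<pws_timecourse> %d timepoints, burst at %s, reference %s\n",
              nrow(x$summary),
              ifelse(is.na(x$burst$burst_timepoint), "none",
                     x$burst$burst_timepoint),
              ifelse(x$reference_subtracted, "subtracted", "NOT subtracted")))
  invisible(x)
}

#' @method tidy pws_timecourse
#' @export
tidy.pws_timecourse <- function(x, ...) x$summary
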