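#' Nanoscale structure map (Sigma_s) from a spectral cube
#'
#' `Sigma_s` is the per-pixel standard deviation of the spectral
#' interference: the wavelength-dependent oscillation of the backscattered
#' signal that encodes nanoscale (sub-diffraction) mass-density
#' heterogeneity. Each pixel's spectrum is detrended and the population
#' standard deviation (divide by the number of wavelengths) of the residual
#' is taken over the wavelength axis.
#'
#' Two detrend modes are provided and recorded in provenance:
#' \describe{
#'   \item{`"mean"` (default)}{subtract the per-pixel spectral mean, so
#'     `Sigma_s` is invariant to a wavelength-independent reflectance
#'     offset.}
#'   \item{`"linear"`}{additionally remove a linear-in-wavelength trend,
#'     suppressing slow reflectance slopes that are not interference.}
#' }
#'
#' @param spectral_cube A normalized spectral `pws_cube` (>= 3 wavelengths).
#' @param detrend `"mean"` or `"linear"`.
#' @return A `pws_map` (`what = "sigma_s"`); pixels with non-finite spectra
#'   are masked.
#' @export
#' @examples
#' m <- acquisition_meta(seq(500, 700, 10), 0.035)
#' arr <- array(0.02, c(21, 4, 4))
#' compute_sigma_s(spectral_cube(arr, m))  # flat spectra: Sigma_s = 0
compute_sigma_s <- function(spectral_cube, detrend = c("mean", "linear")) {
  stopifnot(inherits(spectral_cube, "pws_cube"),
            spectral_cube$kind == "spectral")
  detrend <- match.arg(detrend)
  if (!spectral_cube$normalized) {
    warn("Spectral cube is not flagged as normalized reflectance.")
  }
  arr <- spectral_cube$intensities
  d <- dim(arr)
  x <- arr
  dim(x) <- c(d[1], d[2] * d[3])
  valid <- matrix(colSums(!is.finite(x)) == 0, d[2], d[3])
  if (detrend == "mean") {
    res <- sweep(x, 2, colMeans(x))
  } else {
    wl <- spectral_cube$meta$wavelengths_nm
    basis <- cbind(1, wl - mean(wl))
    res <- x - basis %*% qr.solve(basis, x)
  }
  s <- matrix(sqrt(colMeans(res^2)), d[2], d[3])
  pws_map(s, valid = valid, what = "sigma_s",
          provenance = list(detrend = detrend,
                            wavelength_range_nm = range(spectral_cube$meta$wavelengths_nm),
                            sd_convention = "population (divide by N_lambda)"))
}

#' Summarise Sigma_s over a region of interest
#'
#' Mean and standard error of the mean over the valid pixels of a mask --
#' the per-region summary used for nucleus/cytoplasm comparisons.
#'
#' @param structure_map A `pws_map` (any per-pixel map works).
#' @param mask Logical matrix matching the map shape.
#' @return A tibble with `mean`, `sem`, `n`.
#' @export
sigma_s_roi_summary <- function(structure_map, mask) {
  roi_summary(structure_map, mask, min_pixels = 1L)
}
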