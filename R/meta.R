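#' Acquisition metadata for an image cube
#'
#' Bundles the physical acquisition parameters that every downstream equation
#' needs: wavelength(s), exposure and frame timing, pixel size, the medium
#' refractive index, and the derived optical wavenumber.
#'
#' The wavenumber convention is \eqn{k = 2\pi n / \lambda} with
#' \eqn{\lambda} the *vacuum* wavelength and \eqn{n} the medium refractive
#' index, i.e. the phase rate of light inside the medium. Backscattering
#' doubles the phase sensitivity (phase \eqn{= 2kz}), which is where the
#' \eqn{4k^2} factor in the diffusion relation comes from. Because recovered
#' diffusion coefficients scale as \eqn{1/k^2}, the convention is recorded in
#' the metadata (`k_convention`) and echoed into every output's provenance.
#'
#' Frame timestamps are `frame_index * frame_interval` (0-based index), with
#' intensity attributed to the start of each exposure window.
#'
#' @param wavelengths_nm Vacuum wavelength(s) in nm; one value for a temporal
#'   cube, an increasing vector spanning the spectral range for a spectral
#'   cube. Must lie within 400-800 nm.
#' @param exposure_time_s Camera exposure per frame, seconds.
#' @param frame_interval_s Time between frame starts, seconds. Defaults to
#'   `exposure_time_s` (contiguous acquisition). Must be >= exposure.
#' @param n_frames Number of frames (temporal cubes) or wavelengths (spectral
#'   cubes, where it must match `length(wavelengths_nm)`).
#' @param pixel_size_um Size of one pixel in the sample plane, micrometres.
#' @param medium_ri Refractive index of the medium the scatterers move in
#'   (cells / media are typically 1.33-1.46).
#' @param illumination_na,collection_na Numerical apertures; the collection NA
#'   sets the lateral point-spread width used by the simulator.
#'
#' @return An object of class `pws_meta`: a list with the fields above plus
#'   `acquisition_time_s` (= `n_frames * frame_interval_s`) and
#'   `wavenumber_um` (k in 1/um, for the first wavelength).
#' @export
#' @examples
#' m <- acquisition_meta(550, exposure_time_s = 0.032, n_frames = 201,
#'                       pixel_size_um = 0.25, medium_ri = 1.46)
#' m$wavenumber_um  # 2*pi*1.46/0.55
acquisition_meta <- function(wavelengths_nm,
                             exposure_time_s,
                             frame_interval_s = exposure_time_s,
                             n_frames = length(wavelengths_nm),
                             pixel_size_um = 0.25,
                             medium_ri = 1.46,
                             illumination_na = 0.55,
                             collection_na = 1.4) {
  if (!is.numeric(wavelengths_nm) || length(wavelengths_nm) < 1) {
    abort("`wavelengths_nm` must be a numeric vector.", class = "ipws_metadata_error")
  }
  if (any(wavelengths_nm < 400 | wavelengths_nm > 800)) {
    abort("All wavelengths must lie within 400-800 nm.", class = "ipws_metadata_error")
  }
  if (length(wavelengths_nm) > 1 && any(diff(wavelengths_nm) <= 0)) {
    abort("Spectral wavelengths must be strictly increasing.", class = "ipws_metadata_error")
  }
  stopifnot(exposure_time_s > 0, frame_interval_s > 0, pixel_size_um > 0,
            medium_ri > 0, n_frames >= 1)
  if (exposure_time_s > frame_interval_s * (1 + 1e-9)) {
    abort("`exposure_time_s` cannot exceed `frame_interval_s`.",
          class = "ipws_metadata_error")
  }
  meta <- structure(
    list(
      wavelengths_nm     = as.numeric(wavelengths_nm),
      exposure_time_s    = exposure_time_s,
      frame_interval_s   = frame_interval_s,
      n_frames           = as.integer(n_frames),
      acquisition_time_s = n_frames * frame_interval_s,
      pixel_size_um      = pixel_size_um,
      medium_ri          = medium_ri,
      illumination_na    = illumination_na,
      collection_na      = collection_na,
      wavenumber_um      = wavenumber(wavelengths_nm[1], medium_ri),
      k_convention       = "medium: k = 2*pi*n/lambda_vacuum"
    ),
    class = "pws_meta"
  )
  meta
}

#' Optical wavenumber in the medium
#'
#' \eqn{k = 2\pi n / \lambda}, in 1/um, for a vacuum wavelength in nm.
#'
#' @param wavelength_nm Vacuum wavelength, nm.
#' @param medium_ri Medium refractive index.
#' @return Wavenumber in 1/um.
#' @export
wavenumber <- function(wavelength_nm, medium_ri) {
  stopifnot(wavelength_nm > 0, medium_ri > 0)
  2 * pi * medium_ri / (wavelength_nm * 1e-3)
}

#' @export
print.pws_meta <- function(x, ...) {
  wl <- if (length(x$wavelengths_nm) == 1) {
    sprintf("%g nm", x$wavelengths_nm)
  } else {
    sprintf("%d wavelengths %g-%g nm", length(x$wavelengths_nm),
            min(x$wavelengths_nm), max(x$wavelengths_nm))
  }
  cat(sprintf(
    "<pws_meta> %s | exposure %.4g s, interval %.4g s, %d frames (%.4g s total)\n",
    wl, x$exposure_time_s, x$frame_interval_s, x$n_frames, x$acquisition_time_s))
  cat(sprintf("  pixel %.3g um, n_medium %.3g, k = %.4g 1/um (%s)\n",
              x$pixel_size_um, x$medium_ri, x$wavenumber_um, x$k_convention))
  invisible(x)
}

meta_as_list <- function(meta) {
  unclass(meta)
}

meta_from_list <- function(lst) {
  acquisition_meta(
    wavelengths_nm   = as.numeric(lst$wavelengths_nm),
    exposure_time_s  = as.numeric(lst$exposure_time_s),
    frame_interval_s = as.numeric(lst$frame_interval_s %||% lst$exposure_time_s),
    n_frames         = as.integer(lst$n_frames),
    pixel_size_um    = as.numeric(lst$pixel_size_um %||% 0.25),
    medium_ri        = as.numeric(lst$medium_ri %||% 1.46),
    illumination_na  = as.numeric(lst$illumination_na %||% 0.55),
    collection_na    = as.numeric(lst$collection_na %||% 1.4)
  )
}
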