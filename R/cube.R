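#' Image-cube containers
#'
#' A `pws_cube` wraps a 3-D intensity array with axis order `(t | lambda, y,
#' x)` together with its [acquisition_meta()]. Temporal cubes hold reflectance
#' frames acquired at one wavelength; spectral cubes hold one frame per
#' wavelength spanning (typically) 500-700 nm. Pixel indices are `(row = y,
#' col = x)`. A reference cube is a temporal cube acquired from an empty field
#' of view, used to estimate and subtract instrument noise.
#'
#' @param intensities 3-D numeric array, dims `(n_frames | n_wavelengths, ny,
#'   nx)`. All values must be finite.
#' @param meta A [acquisition_meta()] object. For `temporal_cube` it must
#'   carry exactly one wavelength and `n_frames >= 2`; for `spectral_cube` at
#'   least 3 wavelengths matching `dim(intensities)[1]`.
#' @param normalized Logical; whether intensities are already dimensionless
#'   reflectance (the simulator emits reflectance directly).
#' @param is_reference Logical; marks an empty-field reference cube.
#'
#' @return An object of class `pws_cube` with fields `intensities`, `meta`,
#'   `kind` ("temporal" or "spectral"), `normalized`, `is_reference`, and
#'   `provenance` (a list accumulated by processing steps).
#' @export
#' @examples
#' m <- acquisition_meta(550, 0.032, n_frames = 4)
#' cube <- temporal_cube(array(0.01, c(4, 8, 8)), m)
#' dim(cube$intensities)
temporal_cube <- function(intensities, meta, normalized = TRUE,
                          is_reference = FALSE) {
  new_cube(intensities, meta, kind = "temporal", normalized = normalized,
           is_reference = is_reference)
}

#' @rdname temporal_cube
#' @export
spectral_cube <- function(intensities, meta, normalized = TRUE) {
  new_cube(intensities, meta, kind = "spectral", normalized = normalized,
           is_reference = FALSE)
}

new_cube <- function(intensities, meta, kind, normalized, is_reference,
                     provenance = list()) {
  if (!inherits(meta, "pws_meta")) {
    abort("`meta` must be an `acquisition_meta()` object.",
          class = "ipws_metadata_error")
  }
  if (!is.array(intensities) || length(dim(intensities)) != 3) {
    abort("`intensities` must be a 3-D array with axes (t|lambda, y, x).",
          class = "ipws_format_error")
  }
  if (!all(is.finite(intensities))) {
    abort("Cube intensities must all be finite.", class = "ipws_format_error")
  }
  d <- dim(intensities)
  if (kind == "temporal") {
    if (length(meta$wavelengths_nm) != 1) {
      abort("A temporal cube carries exactly one wavelength.",
            class = "ipws_metadata_error")
    }
    if (d[1] < 2) {
      abort("A temporal cube needs n_frames >= 2.", class = "ipws_format_error")
    }
  } else {
    if (length(meta$wavelengths_nm) < 3) {
      abort("A spectral cube needs at least 3 wavelengths.",
            class = "ipws_metadata_error")
    }
    if (length(meta$wavelengths_nm) != d[1]) {
      abort(sprintf(
        "Spectral axis length (%d) does not match number of wavelengths (%d).",
        d[1], length(meta$wavelengths_nm)), class = "ipws_format_error")
    }
  }
  if (d[1] != meta$n_frames) {
    abort(sprintf("First axis length (%d) does not match meta n_frames (%d).",
                  d[1], meta$n_frames), class = "ipws_format_error")
  }
  structure(
    list(intensities = intensities, meta = meta, kind = kind,
         normalized = isTRUE(normalized), is_reference = isTRUE(is_reference),
         provenance = provenance),
    class = "pws_cube"
  )
}

#' @export
print.pws_cube <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<pws_cube: %s%s> %d x %d px, %d %s, %s\n",
              x$kind, if (x$is_reference) " (reference)" else "",
              d[3], d[2], d[1],
              if (x$kind == "temporal") "frames" else "wavelengths",
              if (x$normalized) "reflectance" else "raw counts"))
  print(x$meta)
  invisible(x)
}

#' @export
dim.pws_cube <- function(x) dim(x$intensities)

cube_spatial_dim <- function(cube) dim(cube$intensities)[2:3]

#' Number of frames / wavelengths in a cube
#' @param cube A `pws_cube`.
#' @return Integer length of the first axis.
#' @export
n_frames <- function(cube) dim(cube$intensities)[1]

assert_same_geometry <- function(a, b, what = "cube") {
  if (!identical(cube_spatial_dim(a), cube_spatial_dim(b))) {
    abort(sprintf("Spatial shapes differ between %ss.", what),
          class = "ipws_format_error")
  }
  invisible(TRUE)
}

#' Per-pixel map container
#'
#' Holds a per-pixel scalar map (`values`, a `ny x nx` matrix), a logical
#' `valid` mask of the same shape, and a `provenance` list recording how it
#' was computed. Invalid pixels carry `NA` in `values`.
#'
#' @param values Numeric matrix.
#' @param valid Logical matrix, same shape (default: all finite values).
#' @param what Short name of the quantity (e.g. "sigma_s", "sigma_t2", "D").
#' @param provenance Named list of processing parameters.
#' @return A `pws_map` object.
#' @export
pws_map <- function(values, valid = NULL, what = "map", provenance = list()) {
  stopifnot(is.matrix(values))
  if (is.null(valid)) valid <- is.finite(values)
  stopifnot(is.logical(valid), identical(dim(valid), dim(values)))
  values[!valid] <- NA_real_
  structure(list(values = values, valid = valid, what = what,
                 provenance = provenance),
            class = "pws_map")
}

#' @export
print.pws_map <- function(x, ...) {
  v <- x$values[x$valid]
  cat(sprintf("<pws_map: %s> %d x %d px, %d valid (%.1f%%)\n", x$what,
              ncol(x$values), nrow(x$values), length(v),
              100 * mean(x$valid)))
  if (length(v)) {
    cat(sprintf("  range %.4g .. %.4g, mean %.4g\n", min(v), max(v), mean(v)))
  }
  invisible(x)
}

#' @export
dim.pws_map <- function(x) dim(x$values)

#' Tidy a per-pixel map into a tibble
#'
#' @param x A `pws_map`.
#' @param ... Unused.
#' @return A tibble with columns `x`, `y` (0-based pixel indices), `value`,
#'   `valid`.
#' @method tidy pws_map
#' @export
tidy.pws_map <- function(x, ...) {
  d <- dim(x$values)
  vals <- as.vector(x$values)
  ok <- as.vector(x$valid)
  tibble::tibble(
    y = rep(seq_len(d[1]) - 1L, times = d[2]),
    x = rep(seq_len(d[2]) - 1L, each = d[1]),
    value = vals,
    valid = ok
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
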