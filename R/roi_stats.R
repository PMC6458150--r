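#' ROI mask constructor
#'
#' Wraps a logical pixel mask with a label. Masks are supplied (drawn,
#' imported, or thresholded); [threshold_mask()] offers a convenience
#' threshold, not a claimed segmentation method.
#'
#' @param mask Logical matrix.
#' @param label One of "nucleus", "cytoplasm", "cell", "background", or a
#'   custom string.
#' @param source Free-text provenance ("manual polygon", "threshold",
#'   "imported", ...).
#' @return A `pws_roi` object.
#' @export
roi_mask <- function(mask, label = "custom", source = "manual") {
  stopifnot(is.logical(mask), is.matrix(mask))
  structure(list(mask = mask, label = label, source = source),
            class = "pws_roi")
}

#' @rdname roi_mask
#' @param map A `pws_map` to threshold.
#' @param quantile_cut Quantile of valid values above which pixels enter the
#'   mask.
#' @export
threshold_mask <- function(map, quantile_cut = 0.5, label = "custom") {
  stopifnot(inherits(map, "pws_map"))
  thr <- quantile(map$values[map$valid], quantile_cut, na.rm = TRUE)
  m <- map$values >= thr & map$valid
  m[is.na(m)] <- FALSE
  roi_mask(m, label = label, source = sprintf("threshold q=%g", quantile_cut))
}

#' Mean and SEM of a map over a region of interest
#'
#' @param map A `pws_map` or a numeric matrix.
#' @param mask Logical matrix (or `pws_roi`) matching the map shape.
#' @param min_pixels Minimum number of valid pixels required.
#' @return A tibble with `mean`, `sem` (sample-SD based), `n`.
#' @export
#' @examples
#' m <- pws_map(matrix(c(2, 4, 1, 1), 2, 2))
#' roi_summary(m, matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))  # mean 3, sem 1
roi_summary <- function(map, mask, min_pixels = 2L) {
  vals <- if (inherits(map, "pws_map")) map$values else map
  ok <- if (inherits(map, "pws_map")) map$valid else is.finite(vals)
  if (inherits(mask, "pws_roi")) mask <- mask$mask
  stopifnot(is.logical(mask), identical(dim(mask), dim(vals)))
  if (!any(mask)) {
    abort("Empty ROI mask.", class = "ipws_domain_error")
  }
  v <- vals[mask & ok]
  if (length(v) < min_pixels) {
    abort(sprintf("ROI has %d valid pixels; need at least %d.",
                  length(v), min_pixels), class = "ipws_domain_error")
  }
  tibble::tibble(mean = mean(v),
                 sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
                 n = length(v))
}

#' Percent change between paired measurements
#'
#' `100 * (after - before) / |before|`; the absolute value in the
#' denominator keeps the sign of the result aligned with the direction of
#' change even for negative baselines.
#'
#' @param before,after Numeric (vectorised); `before` must be nonzero.
#' @return Percent change.
#' @export
#' @examples
#' percent_change(10, 0.21)  # -97.9
percent_change <- function(before, after) {
  if (any(before == 0)) {
    abort("`before` must be nonzero.", class = "ipws_domain_error")
  }
  100 * (after - before) / abs(before)
}

#' Two-tailed t tests (heteroscedastic or paired)
#'
#' `mode = "welch"` performs the heteroscedastic (unequal-variance) Student's
#' t test; `mode = "paired"` the paired test. Both are two-tailed.
#'
#' @param sample_a,sample_b Numeric vectors (n >= 2 each; equal lengths for
#'   paired mode).
#' @param mode "welch" or "paired".
#' @return A tibble with `t`, `p`, `df`, `mode`.
#' @export
t_test <- function(sample_a, sample_b, mode = c("welch", "paired")) {
  mode <- match.arg(mode)
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    abort("Need at least 2 observations per sample.",
          class = "ipws_domain_error")
  }
  if (mode == "paired" && length(sample_a) != length(sample_b)) {
    abort("Paired mode requires equal sample lengths.",
          class = "ipws_domain_error")
  }
  if (mode == "paired") {
    d <- sample_a - sample_b
    if (sd(d) == 0 && mean(d) == 0) {
      # identical paired samples: t = 0, p = 1 by convention
      return(tibble::tibble(t = 0, p = 1, df = length(d) - 1, mode = mode))
    }
    if (sd(d) == 0) {
      abort("Degenerate variance in paired differences.",
            class = "ipws_domain_error")
    }
    ht <- t.test(sample_a, sample_b, paired = TRUE)
  } else {
    if (sd(sample_a) == 0 && sd(sample_b) == 0) {
      if (mean(sample_a) == mean(sample_b)) {
        return(tibble::tibble(t = 0, p = 1,
                              df = length(sample_a) + length(sample_b) - 2,
                              mode = mode))
      }
      abort("Degenerate variance in both samples.",
            class = "ipws_domain_error")
    }
    ht <- t.test(sample_a, sample_b, var.equal = FALSE)
  }
  tibble::tibble(t = unname(ht$statistic), p = ht$p.value,
                 df = unname(ht$parameter), mode = mode)
}

#' Coefficient of determination
#'
#' R^2 of a simple linear regression, computed as the square of the Pearson
#' correlation coefficient.
#'
#' @param x,y Numeric vectors, n >= 3, non-degenerate.
#' @return R^2 in \[0, 1\].
#' @export
r_squared <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    abort("Need at least 3 finite pairs.", class = "ipws_domain_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Zero variance in x or y.", class = "ipws_domain_error")
  }
  cor(x, y)^2
}
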