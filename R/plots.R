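#' Plot a per-pixel map
#'
#' @param object A `pws_map`.
#' @param ... Unused.
#' @return A ggplot raster of the map, invalid pixels blank.
#' @method autoplot pws_map
#' @export
autoplot.pws_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = object$what, x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' Plot an event timing map
#'
#' @param object A `pws_event_map`.
#' @param ... Unused.
#' @return A ggplot raster of onset times; eventless pixels blank.
#' @method autoplot pws_event_map
#' @export
autoplot.pws_event_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$onset_time_s)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90", option = "plasma") +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "onset (s)", x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' Plot recovered-vs-theory agreement for a phantom validation run
#'
#' @param object A `pws_validation`.
#' @param quantity `"D"` or `"sigma_t"`.
#' @param ... Unused.
#' @return A ggplot scatter of recovered vs theoretical values with the
#'   identity line.
#' @method autoplot pws_validation
#' @export
autoplot.pws_validation <- function(object, quantity = c("D", "sigma_t"), ...) {
  quantity <- match.arg(quantity)
  res <- tidy(object)
  if (quantity == "D") {
    res <- dplyr::filter(res, .data$volume_fraction %in% object$d_accuracy_phi)
    p <- ggplot2::ggplot(res, ggplot2::aes(x = .data$true_D, y = .data$D_hat,
                                           colour = factor(.data$radius_nm))) +
      ggplot2::labs(x = "Stokes-Einstein D (um^2/s)",
                    y = "recovered D (um^2/s)", colour = "radius (nm)")
  } else {
    res <- dplyr::mutate(res,
                         theory = sqrt(.data$sigma_t2_theory),
                         measured = sqrt(pmax(.data$sigma_t2_corrected, 0)))
    p <- ggplot2::ggplot(res, ggplot2::aes(x = .data$theory, y = .data$measured,
                                           colour = factor(.data$radius_nm),
                                           shape = factor(.data$glycerol_pct))) +
      ggplot2::labs(x = "analytic Sigma_t", y = "measured Sigma_t (corrected)",
                    colour = "radius (nm)", shape = "% glycerol")
  }
  p + ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                           colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
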