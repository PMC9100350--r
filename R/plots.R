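image_to_df <- function(px) {
  tibble::tibble(x = rep(0:(ncol(px) - 1L), each = nrow(px)),
                 y = rep(0:(nrow(px) - 1L), times = ncol(px)),
                 value = as.vector(px))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a capacitive image
#'
#' Grey-level raster with the image's top-left origin (y increases
#' downwards, as in the pixel coordinate convention).
#'
#' @param object A [capacitive_image()].
#' @param roi Optional [roi_rect()] drawn as an outline.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.capacitive_image <- function(object, roi = NULL, ...) {
  p <- ggplot2::ggplot(image_to_df(as.matrix(object)),
                       ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255), name = "grey") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
  if (!is.null(roi)) {
    p <- p + ggplot2::annotate("rect", xmin = roi$x, xmax = roi$x + roi$w,
                               ymin = roi$y, ymax = roi$y + roi$h,
                               colour = "red", fill = NA, linewidth = 0.6)
  }
  p
}

#' Plot a template-matching score surface
#'
#' @param object A [match_surface()].
#' @param ... Unused.
#' @return A ggplot object with the best match marked.
#' @export
autoplot.match_surface <- function(object, ...) {
  bm <- best_match(object)
  ggplot2::ggplot(image_to_df(object$scores),
                  ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "score") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::annotate("point", x = bm$location[["x"]], y = bm$location[["y"]],
                      colour = "red", shape = 4, size = 3) +
    ggplot2::labs(title = sprintf("%s%s surface", object$method,
                                  if (object$literal) " (literal)" else "")) +
    ggplot2::theme_minimal()
}

#' Plot TEWL means with error bars
#'
#' Mean ± SD per site and timepoint, one panel per instrument — the
#' standard presentation of repeated TEWL measurements.
#'
#' @param report A [tewl_summary()] or [site_report()] tibble.
#' @return A ggplot object.
#' @export
plot_tewl <- function(report) {
  ggplot2::ggplot(report,
                  ggplot2::aes(.data$timepoint, .data$mean,
                               group = .data$site_id, colour = .data$site_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::facet_wrap(~instrument, scales = "free_y") +
    ggplot2::labs(y = expression(TEWL ~ (g ~ m^-2 ~ h^-1)), x = NULL,
                  colour = "site") +
    ggplot2::theme_minimal()
}

#' Plot an ROI permittivity histogram
#'
#' @param stats A [roi_stats()] result.
#' @return A ggplot object.
#' @export
plot_roi_histogram <- function(stats) {
  h <- stats$histogram
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$bin_low + .data$bin_high) / 2,
                                  y = .data$count)) +
    ggplot2::geom_col(width = h$bin_high[1] - h$bin_low[1], fill = "steelblue") +
    ggplot2::labs(x = "relative permittivity", y = "pixels") +
    ggplot2::theme_minimal()
}

#' Plot a PCA distance ranking
#'
#' @param ranking A [rank_sites()] tibble.
#' @return A ggplot object: ascending distances, nearest at the top.
#' @export
plot_pca_ranking <- function(ranking) {
  ggplot2::ggplot(ranking,
                  ggplot2::aes(x = .data$d,
                               y = stats::reorder(.data$label, -.data$d))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "PCA distance d", y = NULL) +
    ggplot2::theme_minimal()
}
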