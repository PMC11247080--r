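#' Plot a raster image or mask with ggplot2
#'
#' @param object a `raster_image`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot raster_image
#' @export
autoplot.raster_image <- function(object, ...) {
  h <- img_height(object); w <- img_width(object)
  df <- tidyr::expand_grid(row = seq_len(h), col = seq_len(w))
  if (img_bands(object) == 3L) {
    df$fill <- grDevices::rgb(as.vector(img_band(object, 1)),
                              as.vector(img_band(object, 2)),
                              as.vector(img_band(object, 3)))
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
      ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
      ggplot2::scale_fill_identity()
  } else {
    df$value <- as.vector(img_band(object, 1))
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
      ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
      ggplot2::scale_fill_gradient(low = "black", high = "white")
  }
  p + ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Heatmap of a crop confusion matrix
#'
#' @param object a `crop_confusion` matrix.
#' @param ... unused.
#' @return a ggplot object (tile heatmap, rows truth, columns prediction).
#' @method autoplot crop_confusion
#' @export
autoplot.crop_confusion <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame.table(unclass(object),
                                              responseName = "count"))
  names(df)[1:2] <- c("truth", "predicted")
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "predicted (top-1)", y = "dominant (truth)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Bar chart of crop scores in a recommendation
#'
#' @param object a recommendation tibble from [recommend()].
#' @param ... unused.
#' @return a ggplot object, facetted per location when several are present.
#' @export
plot_recommendation <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(stats::reorder(.data$crop, -.data$rank),
                                    .data$score)) +
    ggplot2::geom_col(fill = "forestgreen") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "rule-vote score") +
    ggplot2::theme_minimal()
  if ("location_name" %in% names(object)) {
    p <- p + ggplot2::facet_wrap(~location_name, scales = "free_y")
  }
  p
}
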