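#' Plot a frame with detected contours
#'
#' @param img intensity matrix in `[0, 1]`.
#' @param detections optional detections tibble whose snake outlines are
#'   overlaid.
#' @param truth optional ground-truth tibble whose centres are overlaid.
#' @return A ggplot object.
#' @export
plot_frame <- function(img, detections = NULL, truth = NULL) {
  df <- tidyr::expand_grid(y = seq_len(nrow(img)) - 1,
                           x = seq_len(ncol(img)) - 1)
  df$value <- as.vector(t(img))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1), guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(detections) && nrow(detections) > 0) {
    outlines <- purrr::map_dfr(seq_len(nrow(detections)), function(i) {
      td <- tidy(detections$polygon[[i]])
      td$label <- detections$label[i]
      td
    })
    p <- p + ggplot2::geom_polygon(
      data = outlines,
      ggplot2::aes(.data$x, .data$y, group = .data$label),
      fill = NA, colour = "yellow", linewidth = 0.4
    )
  }
  if (!is.null(truth) && nrow(truth) > 0) {
    p <- p + ggplot2::geom_point(
      data = truth, ggplot2::aes(.data$x, .data$y),
      colour = "red", shape = 3, size = 1.5
    )
  }
  p
}

#' Per-frame cell-count plot for a detections or traces table
#'
#' @param tab tibble with a `frame` column.
#' @return A ggplot object.
#' @export
plot_counts <- function(tab) {
  df <- dplyr::count(tab, .data$frame)
  ggplot2::ggplot(df, ggplot2::aes(.data$frame, .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "frame", y = "cells") +
    ggplot2::theme_minimal()
}
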