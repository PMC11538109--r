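# ggplot2 visualizations of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a persistence barcode
#'
#' One horizontal segment per bar, from birth to death on the filtration
#' axis (negative distance to the root); longer bars are longer branches.
#'
#' @param object a [compute_barcode()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.barcode <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$bar <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$bar)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$birth, xend = .data$death,
                                       yend = .data$bar),
                          linewidth = 1.2, colour = "#2c7fb8") +
    ggplot2::labs(x = "filtration value  -dist(x, root)  [um]", y = "bar",
                  title = "Branch decomposition barcode") +
    ggplot2::theme_minimal()
}

#' Plot an embedded vessel graph
#'
#' Branch polylines with junction/leaf vertices, in image coordinates
#' (y axis flipped so the plot matches the image orientation). Optionally
#' drawn over the source image.
#'
#' @param object an [embedded_graph()].
#' @param image optional background matrix.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.embedded_graph <- function(object, image = NULL, ...) {
  segs <- purrr::imap_dfr(object$edges$geom, function(g, i) {
    tibble::tibble(edge = i, x = g[, 1], y = g[, 2])
  })
  p <- ggplot2::ggplot()
  if (!is.null(image)) {
    df <- tibble::tibble(
      x = rep(seq_len(ncol(image)), each = nrow(image)),
      y = rep(seq_len(nrow(image)), ncol(image)),
      value = as.vector(image))
    p <- p + ggplot2::geom_raster(data = df,
                                  ggplot2::aes(.data$x, .data$y,
                                               fill = .data$value)) +
      ggplot2::scale_fill_gradient(low = "black", high = "grey80",
                                   guide = "none")
  }
  if (nrow(segs) > 0) {
    p <- p + ggplot2::geom_path(data = segs,
                                ggplot2::aes(.data$x, .data$y,
                                             group = .data$edge),
                                colour = "#e31a1c", linewidth = 0.7)
  }
  if (nrow(object$vertices) > 0) {
    p <- p + ggplot2::geom_point(data = object$vertices,
                                 ggplot2::aes(.data$x, .data$y),
                                 colour = "#fd8d3c", size = 1.4)
  }
  p + ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::labs(x = "x [px]", y = "y [px]") +
    ggplot2::theme_minimal()
}

#' Plot per-plane invasion probabilities
#'
#' @param object a [classify_stack()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.invasion_call <- function(object, ...) {
  thr <- attr(object, "threshold")
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$plane, .data$probability)) +
    ggplot2::geom_hline(yintercept = thr, linetype = 2, colour = "grey40") +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$invaded), size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "#2c7fb8",
                                            `TRUE` = "#e31a1c")) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "plane (0 = top)", y = "invasion probability") +
    ggplot2::theme_minimal()
}
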