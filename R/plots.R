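# autoplot methods for connectivity matrices and thresholded graphs.

#' @method autoplot ctc_connectivity
#' @export
autoplot.ctc_connectivity <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region_a, y = .data$region_b,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Fisher z",
                  title = "Functional connectivity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @method autoplot ctc_graph
#' @export
autoplot.ctc_graph <- function(object, ...) {
  n <- length(object$regions)
  ang <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  pos <- data.frame(node = object$regions, x = cos(ang), y = sin(ang),
                    module = if (is.null(object$partition)) "all" else
                      unname(object$partition[object$regions]))
  e <- tidy(object)
  p <- ggplot2::ggplot(pos, ggplot2::aes(x = .data$x, y = .data$y))
  if (nrow(e)) {
    seg <- merge(merge(e, pos[1:3], by.x = "region_a", by.y = "node"),
                 pos[1:3], by.x = "region_b", by.y = "node",
                 suffixes = c("", "end"))
    p <- p + ggplot2::geom_segment(
      data = seg, ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                               yend = .data$yend), colour = "grey60")
  }
  p + ggplot2::geom_label(ggplot2::aes(label = .data$node,
                                       colour = .data$module), size = 3) +
    ggplot2::coord_equal() + ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("Density %.2f", object$density))
}
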