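# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Violin view of observed vs null within-cluster similarity
#'
#' Mirrors the usual presentation of community-coherence validation: one
#' violin for the observed per-cluster similarities, one for the pooled
#' random-grouping null.
#'
#' @param object a [validate_communities()] result.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot tcmnet_validation
#' @export
autoplot.tcmnet_validation <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$similarity,
                                   fill = .data$group)) +
    ggplot2::geom_violin(alpha = 0.6, scale = "width", na.rm = TRUE) +
    ggplot2::geom_boxplot(width = 0.12, outlier.shape = NA, fill = "white",
                          na.rm = TRUE) +
    ggplot2::labs(
      title = sprintf("Within-community %s similarity vs random grouping",
                      object$kind),
      subtitle = sprintf("medians %.3f vs %.3f, Wilcoxon p = %.3g",
                         object$observed_median, object$null_median,
                         object$p_value),
      x = NULL, y = "mean pairwise similarity"
    ) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Community-level view of a reduced network
#'
#' Communities on a circle, point size by member count, edge width by summed
#' inter-community weight.
#'
#' @param object a [reduce_graph()] result.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot tcmnet_reduced
#' @export
autoplot.tcmnet_reduced <- function(object, ...) {
  nodes <- object$nodes
  k <- nrow(nodes)
  theta <- seq(0, 2 * pi, length.out = k + 1)[seq_len(k)]
  nodes$x <- cos(theta)
  nodes$y <- sin(theta)
  edges <- object$edges |>
    dplyr::left_join(dplyr::select(nodes, from = "community", x0 = "x", y0 = "y"),
                     by = "from") |>
    dplyr::left_join(dplyr::select(nodes, to = "community", x1 = "x", y1 = "y"),
                     by = "to")
  p <- ggplot2::ggplot()
  if (nrow(edges)) {
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, linewidth = .data$weight),
      color = "grey60", alpha = 0.7
    )
  }
  p +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$n_members),
                        color = "steelblue") +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = 1.15 * .data$x, y = 1.15 * .data$y,
                                    label = .data$community)) +
    ggplot2::scale_linewidth(range = c(0.3, 2)) +
    ggplot2::coord_equal(xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3)) +
    ggplot2::labs(size = "members", linewidth = "inter-community weight") +
    ggplot2::theme_void()
}

#' Degree distribution of a projected network
#'
#' @param g an `igraph`, typically from [project()].
#' @param bins histogram bins.
#' @return a ggplot.
#' @export
plot_degree_distribution <- function(g, bins = 30) {
  df <- degree_stats(g)$degrees
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", color = "white") +
    ggplot2::labs(x = "degree", y = "nodes") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
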