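#' Bar chart of per-pathway crosstalk degree
#'
#' @param edges Edge tibble from [crosstalk_network()].
#' @param pathways Optional full pathway id vector (isolated pathways shown
#'   with degree zero).
#' @return A ggplot object.
#' @export
plot_crosstalk_degree <- function(edges, pathways = NULL) {
  deg <- crosstalk_degree(edges, pathways)
  ggplot2::ggplot(deg, ggplot2::aes(
    x = stats::reorder(.data$pathway, .data$degree), y = .data$degree)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Crosstalk degree") +
    ggplot2::theme_minimal()
}

#' Degree-distribution plot of a topology summary
#'
#' Log-log degree histogram with the least-squares power-law fit overlaid,
#' the standard visual check of scale-free structure.
#'
#' @param object A [pmsn_topology()] result.
#' @param type Node class to plot: `"all"` (default), `"mirna"` or
#'   `"pathway"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pmsn_topology <- function(object, type = "all", ...) {
  hist <- filter(object$histogram, .data$type == !!type, .data$degree > 0)
  p <- ggplot2::ggplot(hist, ggplot2::aes(x = .data$degree, y = .data$count)) +
    ggplot2::geom_point(color = "steelblue") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Degree", y = "Frequency") +
    ggplot2::theme_minimal()
  pl <- object$powerlaw
  if (type == "all" && is.finite(pl$slope %||% NA_real_)) {
    p <- p + ggplot2::geom_line(
      data = mutate(hist, count = 10^(pl$intercept + pl$slope * log10(.data$degree))),
      color = "firebrick")
  }
  p
}

#' Betweenness-centrality distribution of a PMSN
#'
#' @param topology A [pmsn_topology()] result.
#' @param bins Histogram bin count.
#' @return A ggplot object.
#' @export
plot_betweenness <- function(topology, bins = 20) {
  ggplot2::ggplot(topology$nodes, ggplot2::aes(x = .data$betweenness)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", color = "white") +
    ggplot2::labs(x = "Normalized betweenness centrality", y = "Nodes") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
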