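#' Plot a co-occurrence network
#'
#' Fruchterman-Reingold layout (seeded) with node size proportional to
#' record frequency, edge width to co-occurrence weight, and colour by
#' term category.
#'
#' @param object A [conet()].
#' @param seed Layout seed.
#' @param label_top Label the `label_top` highest-frequency nodes.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.conet <- function(object, seed = 1L, label_top = 10, ...) {
  g <- as_igraph(object)
  xy <- withr::with_seed(seed, igraph::layout_with_fr(g))
  nodes <- dplyr::mutate(object$nodes,
                         x = xy[, 1], y = xy[, 2],
                         label = dplyr::if_else(
                           dplyr::min_rank(dplyr::desc(.data$frequency)) <= label_top,
                           .data$term, NA_character_))
  pos <- setNames(seq_len(nrow(nodes)), nodes$term)
  edges <- dplyr::mutate(object$edges,
                         x = nodes$x[pos[.data$from]],
                         y = nodes$y[pos[.data$from]],
                         xend = nodes$x[pos[.data$to]],
                         yend = nodes$y[pos[.data$to]])
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$weight),
      colour = "grey70", alpha = 0.6) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$frequency,
                   colour = .data$category)) +
    ggplot2::geom_text(
      data = nodes[!is.na(nodes$label), ],
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
      size = 3, vjust = -1) +
    ggplot2::scale_linewidth(range = c(0.2, 2)) +
    ggplot2::theme_void() +
    ggplot2::labs(size = "records", colour = NULL, linewidth = "co-occurrence")
}

#' Plot a sensitivity sweep
#'
#' Faceted metric-vs-threshold lines for the headline metrics of a
#' [threshold_sweep()].
#'
#' @param object A `conet_sweep`.
#' @param metrics Metric columns to facet.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.conet_sweep <- function(object,
                                 metrics = c("n_edges", "avg_degree",
                                             "density", "n_components",
                                             "modularity",
                                             "description_length"),
                                 ...) {
  long <- tidyr::pivot_longer(as_tibble(object)[, c("min_weight", metrics)],
                              -"min_weight", names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(.data$min_weight, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "edge-weight threshold", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a detection-rate table
#'
#' Horizontal bar chart of detection rates per term with per-sex rates
#' overlaid as points.
#'
#' @param data Output of [condition_table()].
#' @param top_n Show the `top_n` most frequent terms.
#' @return A ggplot.
#' @export
plot_detection_rates <- function(data, top_n = 20) {
  data <- head(dplyr::arrange(data, dplyr::desc(.data$count)), top_n)
  long <- tidyr::pivot_longer(data[, c("term", "male_rate", "female_rate")],
                              -"term", names_to = "sex", values_to = "rate")
  long$sex <- sub("_rate", "", long$sex)
  ggplot2::ggplot(data,
                  ggplot2::aes(y = stats::reorder(.data$term, .data$rate))) +
    ggplot2::geom_col(ggplot2::aes(x = .data$rate), fill = "grey80") +
    ggplot2::geom_point(data = long,
                        ggplot2::aes(x = .data$rate, colour = .data$sex)) +
    ggplot2::labs(x = "detection rate (%)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
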