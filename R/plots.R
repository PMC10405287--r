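# ggplot2 displays: network edge plots, community-colored nodes, and the
# stability matrix heatmap.

# fixed circular layout so node positions match across networks
circle_layout <- function(labels) {
  k <- length(labels)
  angle <- pi / 2 - 2 * pi * (seq_len(k) - 1L) / k
  tibble::tibble(node = labels, x = cos(angle), y = sin(angle))
}

#' Plot a partial-correlation network
#'
#' Nodes on a fixed circle; edges with `|pcor|` above the display threshold
#' drawn with width proportional to magnitude, solid for positive and
#' dashed for negative weights. If a partition is supplied, nodes are
#' colored by community and edges are classed within/between community.
#'
#' @param object An `ef_network`.
#' @param partition Optional `ef_partition`/`ef_modal_partition` coloring.
#' @param display_threshold Hide edges with `|weight|` at or below this
#'   value (default 0.1; display only — analyses always use all edges).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ef_network
#' @export
autoplot.ef_network <- function(object, partition = NULL,
                                display_threshold = 0.1, ...) {
  layout <- circle_layout(object$node_labels)
  edges <- edge_list(object, display_threshold) |>
    dplyr::filter(.data$displayed) |>
    dplyr::left_join(dplyr::rename(layout, xa = "x", ya = "y"),
                     by = c(from = "node")) |>
    dplyr::left_join(dplyr::rename(layout, xb = "x", yb = "y"),
                     by = c(to = "node")) |>
    dplyr::mutate(sign = ifelse(.data$weight >= 0, "positive", "negative"))
  nodes <- layout
  if (!is.null(partition)) {
    pt <- tidy(partition)
    nodes <- dplyr::left_join(nodes, pt, by = "node")
    nodes$community <- factor(nodes$community)
    comm_of <- setNames(pt$community, pt$node)
    edges$within <- comm_of[edges$from] == comm_of[edges$to]
  }
  p <- ggplot2::ggplot()
  if (nrow(edges)) {
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb, linewidth = abs(.data$weight),
                   linetype = .data$sign,
                   color = if (!is.null(partition))
                     ifelse(.data$within, "within", "between") else "edge"),
      alpha = 0.8)
  }
  p <- p +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y,
                   fill = if (!is.null(partition)) .data$community else "node"),
      shape = 21, size = 9, color = "grey20") +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = 1.25 * .data$x, y = 1.25 * .data$y,
                   label = .data$node), size = 3) +
    ggplot2::scale_linewidth(range = c(0.3, 2.5), guide = "none") +
    ggplot2::scale_linetype_manual(
      values = c(positive = "solid", negative = "dashed"), guide = "none") +
    ggplot2::coord_equal(xlim = c(-1.6, 1.6), ylim = c(-1.6, 1.6)) +
    ggplot2::theme_void() +
    ggplot2::labs(
      title = sprintf("%s, timepoint %s", object$cohort, object$timepoint),
      caption = sprintf("|pcor| <= %.2f not displayed", display_threshold))
  if (is.null(partition)) {
    p <- p + ggplot2::guides(fill = "none", color = "none")
  } else {
    p <- p + ggplot2::scale_color_manual(
      values = c(within = "grey20", between = "firebrick"), name = NULL)
  }
  p
}

#' Heatmap of the network-stability correlation matrix
#'
#' @param object An `ef_stability`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ef_stability
#' @export
autoplot.ef_stability <- function(object, ...) {
  ids <- object$network_ids
  d <- tidy(object)
  d_full <- dplyr::bind_rows(
    d,
    dplyr::rename(d, network_a = "network_b", network_b = "network_a"),
    tibble::tibble(network_a = ids, network_b = ids, r = 1,
                   ci_low = 1, ci_high = 1))
  d_full$network_a <- factor(d_full$network_a, levels = ids)
  d_full$network_b <- factor(d_full$network_b, levels = rev(ids))
  ggplot2::ggplot(d_full,
                  ggplot2::aes(x = .data$network_a, y = .data$network_b,
                               fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 2.4) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0,
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = "edge-weight r",
                  title = "Cross-network edge-weight correlations") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Staircase trajectory plot for one adaptive-window run
#'
#' Shows the response deadline over trials with feedback classes marked —
#' useful for eyeballing staircase convergence.
#'
#' @param trials Output of [simulate_adaptive_window_task()].
#' @return A ggplot object.
#' @export
plot_staircase <- function(trials) {
  ggplot2::ggplot(trials,
                  ggplot2::aes(x = .data$trial_index, y = .data$window_ms)) +
    ggplot2::geom_step(color = "grey40") +
    ggplot2::geom_point(
      data = dplyr::filter(trials, !is.na(.data$rt_ms)),
      ggplot2::aes(y = .data$rt_ms, color = .data$feedback), size = 0.8) +
    ggplot2::scale_color_manual(values = c(correct = "forestgreen",
                                           late = "orange",
                                           incorrect = "firebrick")) +
    ggplot2::labs(x = "trial", y = "ms", color = "feedback",
                  title = unique(trials$task)) +
    ggplot2::theme_minimal()
}
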