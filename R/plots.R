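#' Plot a bipartite drug-target graph
#'
#' Two-column layout with targets on the left (pink circles, sized by
#' network degree when available) and drugs on the right (blue squares),
#' mirroring the conventions of the published figures.
#'
#' @param object A `pad_bipartite` graph.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pad_bipartite
#' @export
autoplot.pad_bipartite <- function(object, ...) {
  nodes <- object$nodes
  nodes$x <- ifelse(nodes$role == "target", 0, 1)
  nodes$y <- stats::ave(seq_len(nrow(nodes)), nodes$role,
                        FUN = function(i) seq_along(i) / (length(i) + 1))
  pos <- setNames(split(nodes[, c("x", "y")], seq_len(nrow(nodes))),
                  nodes$node)
  seg <- tibble::tibble(
    x = 0, xend = 1,
    y = vapply(object$edges$gene, function(g) pos[[g]]$y, 0),
    yend = vapply(object$edges$drug, function(d) pos[[d]]$y, 0))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend),
      color = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$role,
                   shape = .data$role),
      size = 3) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x + ifelse(.data$role == "target",
                                        -0.05, 0.05),
                   y = .data$y, label = .data$node,
                   hjust = ifelse(.data$role == "target", 1, 0)),
      size = 2.6) +
    ggplot2::scale_shape_manual(values = c(target = 21, drug = 22)) +
    ggplot2::scale_fill_manual(values = c(target = "pink",
                                          drug = "steelblue")) +
    ggplot2::xlim(-0.6, 1.6) +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Drug-target bipartite network")
}

#' Plot candidate genes by network degree
#'
#' @param object A `pad_candidates` table.
#' @param ... Unused.
#' @return A ggplot bar chart, genes ordered by the table's degree
#'   ranking, absent-from-network genes marked.
#' @method autoplot pad_candidates
#' @export
autoplot.pad_candidates <- function(object, ...) {
  df <- tibble::tibble(
    gene = factor(object$gene, levels = rev(object$gene)),
    degree = object$degree,
    membership = ifelse(object$in_network, "in network", "absent"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree, y = .data$gene,
                                   fill = .data$membership)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c("in network" = "grey30",
                                          "absent" = "grey75")) +
    ggplot2::labs(x = "network degree", y = NULL,
                  title = sprintf("%s candidates (%s)",
                                  attr(object, "strategy"),
                                  attr(object, "set_id"))) +
    ggplot2::theme_minimal()
}

#' Degree distribution of an interaction network
#'
#' @param network A [pad_network()].
#' @return A ggplot histogram of node degrees.
#' @export
plot_degree_distribution <- function(network) {
  df <- degree_table(network)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "steelblue",
                            color = "white") +
    ggplot2::labs(x = "degree", y = "nodes",
                  title = sprintf("Degree distribution: %s", network$name)) +
    ggplot2::theme_minimal()
}
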