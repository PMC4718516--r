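# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a constructed network
#'
#' Fruchterman-Reingold layout with nodes colored by role; layout is
#' seeded so repeated plots are identical.
#'
#' @param object A `dg_network`.
#' @param label Draw node labels (sensible for small networks only).
#' @param rng_seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dg_network
#' @export
autoplot.dg_network <- function(object, label = nrow(object$nodes) <= 50,
                                rng_seed = 42, ...) {
  g <- net_igraph(object)
  xy <- with_seed(rng_seed, igraph::layout_with_fr(g))
  nodes <- mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  pos <- stats::setNames(seq_len(nrow(nodes)), nodes$id)
  segs <- tibble(
    x = nodes$x[pos[object$edges$source]],
    y = nodes$y[pos[object$edges$source]],
    xend = nodes$x[pos[object$edges$target]],
    yend = nodes$y[pos[object$edges$target]]
  )
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      color = "grey70", linewidth = 0.3
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, color = .data$role),
      size = 2.5
    ) +
    ggplot2::labs(title = object$name, color = "role") +
    ggplot2::theme_void()
  if (label) {
    p <- p + ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$id),
      size = 2.5, vjust = -1
    )
  }
  p
}

#' Volcano plot of a moderated contrast
#'
#' Log2 fold change against -log10 moderated p, with the significance tier
#' marked.
#'
#' @param stats A `moderated_stats` object.
#' @param alpha Highlight threshold.
#' @return A ggplot object.
#' @export
plot_volcano <- function(stats, alpha = 0.01) {
  tab <- mutate(tidy(stats), significant = .data$p < alpha)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$lfc,
                                    y = -log10(.data$p),
                                    color = .data$significant)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_color_manual(values = c("FALSE" = "grey60",
                                           "TRUE" = "firebrick")) +
    ggplot2::labs(
      x = "log2 fold change (case - control)",
      y = expression(-log[10] ~ "moderated p"),
      title = stats$contrast,
      color = sprintf("p < %g", alpha)
    ) +
    ggplot2::theme_minimal()
}

#' Dot plot of an enrichment table
#'
#' Fold enrichment against gene set, sized by overlap and colored by
#' adjusted p.
#'
#' @param records Enrichment tibble from [enrich()].
#' @param max_sets Show at most this many sets (best adjusted p first).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(records, max_sets = 20) {
  records <- head(arrange(records, .data$p_adj), max_sets)
  records <- mutate(records,
                    name = stats::reorder(.data$name, -.data$p_adj))
  ggplot2::ggplot(records, ggplot2::aes(x = .data$fold, y = .data$name,
                                        size = .data$k,
                                        color = -log10(.data$p_adj))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "fold enrichment", y = NULL, size = "overlap",
                  color = expression(-log[10] ~ p[adj])) +
    ggplot2::theme_minimal()
}
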