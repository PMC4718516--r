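# Broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a moderated-statistics fit
#'
#' @param x A `moderated_stats` object.
#' @param ... Unused.
#' @return Per-gene tibble: `gene`, `lfc`, `t_mod`, `p`, `s2`, `s2_post`,
#'   `df_total`.
#' @method tidy moderated_stats
#' @export
tidy.moderated_stats <- function(x, ...) x$table

#' Glance at a moderated-statistics fit
#'
#' @param x A `moderated_stats` object.
#' @param ... Unused.
#' @return One-row tibble: `contrast`, `d0`, `s0_2`, `n_genes`.
#' @method glance moderated_stats
#' @export
glance.moderated_stats <- function(x, ...) {
  tibble(contrast = x$contrast, d0 = x$d0, s0_2 = x$s0_2,
         n_genes = nrow(x$table))
}

#' Tidy a seed-gene set
#'
#' @param x A `seed_gene_set`.
#' @param ... Unused.
#' @return Provenance tibble: `gene`, `contrast`, `p`.
#' @method tidy seed_gene_set
#' @export
tidy.seed_gene_set <- function(x, ...) x$provenance

#' Glance at a seed-gene set
#'
#' @param x A `seed_gene_set`.
#' @param ... Unused.
#' @return One-row tibble: `n_genes`, `tier`, `n_contrast_hits`.
#' @method glance seed_gene_set
#' @export
glance.seed_gene_set <- function(x, ...) {
  tibble(n_genes = length(x$genes), tier = x$tier,
         n_contrast_hits = nrow(x$provenance))
}

#' Tidy a constructed network
#'
#' @param x A `dg_network`.
#' @param ... Unused.
#' @return The node tibble with per-node induced degree attached.
#' @method tidy dg_network
#' @export
tidy.dg_network <- function(x, ...) {
  g <- net_igraph(x)
  deg <- igraph::degree(g)
  mutate(x$nodes, degree = unname(deg[.data$id]))
}

#' Glance at a constructed network
#'
#' @param x A `dg_network`.
#' @param ... Unused.
#' @return One-row tibble: `name`, `n_nodes`, `n_edges`, `avg_degree`,
#'   `n_components`.
#' @method glance dg_network
#' @export
glance.dg_network <- function(x, ...) {
  g <- net_igraph(x)
  tibble(
    name = x$name,
    n_nodes = nrow(x$nodes),
    n_edges = igraph::ecount(g),
    avg_degree = if (nrow(x$nodes) > 0) average_degree(x) else NA_real_,
    n_components = if (nrow(x$nodes) > 0) {
      igraph::components(g)$no
    } else {
      0L
    }
  )
}
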