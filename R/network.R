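# Construction of the three analysis networks from seed genes and the
# interaction database: direct-interaction, shortest-path (SPNW) and the
# compact SPNW.

induced_edges <- function(db, ids) {
  filter(db$edges, .data$source %in% ids & .data$target %in% ids)
}

node_roles <- function(db, ids, seed_set) {
  kind <- stats::setNames(db$nodes$kind, db$nodes$id)
  tibble(
    id = sort(ids),
    role = dplyr::case_when(
      sort(ids) %in% seed_set ~ "seed",
      kind[sort(ids)] == "miRNA" ~ "miRNA",
      TRUE ~ "connector"
    )
  )
}

#' Direct-interaction network over seed genes
#'
#' The subgraph of the interaction database induced on the seed genes. By
#' default seeds with no induced interaction are dropped, so the result
#' contains only the directly interconnected core of the seed set.
#'
#' @param seeds A `seed_gene_set` or character vector.
#' @param db An [interaction_db()].
#' @param drop_isolated Remove seeds of induced degree zero.
#' @return A [dg_network()] with every node in role `seed`.
#' @export
direct_interaction_network <- function(seeds, db, drop_isolated = TRUE) {
  ids <- seed_ids(seeds)
  if (length(ids) == 0) dg_stop("Seed set is empty.")
  present <- intersect(ids, db$nodes$id)
  if (length(present) == 0) {
    dg_stop(sprintf(
      "None of the %d seed genes occur in the interaction database.",
      length(ids)
    ))
  }
  miss <- length(ids) - length(present)
  if (miss > 0) {
    dg_warn(sprintf("%d of %d seeds (%.0f%%) absent from the database.",
                    miss, length(ids), 100 * miss / length(ids)))
  }
  edges <- induced_edges(db, present)
  nodes <- if (drop_isolated) {
    intersect(present, unique(c(edges$source, edges$target)))
  } else {
    present
  }
  dg_network(
    tibble(id = sort(nodes), role = "seed"),
    filter(edges, .data$source %in% nodes & .data$target %in% nodes),
    name = "direct"
  )
}

#' Shortest-path network (SPNW)
#'
#' Expands high-degree seeds with connector nodes: (1) qualifying seeds are
#' those whose degree in the full database graph reaches `min_db_degree`;
#' (2) for every unordered qualifying pair at shortest-path distance at most
#' `max_len` (undirected simple view), every node lying on any shortest
#' path between them is included, non-seeds tagged as connectors; (3) the
#' edge set is the database subgraph induced on the included nodes. Taking
#' all shortest paths, not one arbitrary path per pair, keeps the result
#' deterministic.
#'
#' @param seeds A `seed_gene_set` or character vector.
#' @param db An [interaction_db()].
#' @param min_db_degree Seed degree cutoff, measured on the full database.
#' @param max_len Maximum shortest-path length between a qualifying pair.
#' @return A [dg_network()] with roles `seed` / `connector` / `miRNA`.
#' @export
shortest_path_network <- function(seeds, db, min_db_degree = 25,
                                  max_len = 2) {
  if (min_db_degree < 0 || max_len < 1) {
    dg_stop("Need min_db_degree >= 0 and max_len >= 1.")
  }
  ids <- seed_ids(seeds)
  present <- intersect(ids, db$nodes$id)
  if (length(present) == 0) dg_stop("No seed occurs in the database.")

  g <- db_igraph(db)
  deg <- igraph::degree(g)
  qual <- present[deg[present] >= min_db_degree]
  if (length(qual) == 0) {
    dg_stop(sprintf(
      "No seed reaches database degree %d (max observed seed degree: %d).",
      min_db_degree, max(deg[present])
    ))
  }

  dist_all <- igraph::distances(g, v = qual)
  dist_q <- dist_all[, qual, drop = FALSE]
  include <- character(0)
  node_names <- colnames(dist_all)
  if (length(qual) >= 2) {
    for (i in seq_len(length(qual) - 1)) {
      for (j in seq(i + 1, length(qual))) {
        d <- dist_q[i, j]
        if (is.finite(d) && d <= max_len) {
          on_path <- dist_all[i, ] + dist_all[j, ] == d
          include <- c(include, node_names[on_path])
        }
      }
    }
  }
  include <- unique(include)
  if (length(include) == 0) {
    dg_warn("No qualifying seed pair within max_len; the SPNW is empty.")
  }
  dg_network(
    node_roles(db, include, ids),
    induced_edges(db, include),
    name = "spnw"
  )
}

#' Compact version of a shortest-path network
#'
#' Starts from the subgraph induced on the nodes worth keeping (the
#' categorized genes) and greedily restores connectivity: while more than
#' one component contains keep nodes and the budget remains, add the SPNW
#' connector adjacent to the largest number of currently-separate
#' keep-containing components (ties broken by higher SPNW degree, then
#' lexicographically smaller id). A Steiner-style heuristic standing in for
#' manual curation of "a few additional connecting genes".
#'
#' @param spnw A [dg_network()] as from [shortest_path_network()].
#' @param keep Node ids to retain (must be SPNW nodes).
#' @param max_extra Budget of added connectors.
#' @return A [dg_network()]; added connectors keep their SPNW role.
#' @export
compact_network <- function(spnw, keep, max_extra = Inf) {
  keep <- sort(unique(norm_gene_id(keep)))
  if (length(keep) == 0) dg_stop("keep set is empty.")
  stray <- setdiff(keep, spnw$nodes$id)
  if (length(stray) > 0) {
    dg_stop(sprintf("keep node(s) outside the SPNW: %s",
                    paste(head(stray, 3), collapse = ", ")))
  }
  g <- net_igraph(spnw)
  spnw_deg <- igraph::degree(g)

  current <- keep
  added <- character(0)
  repeat {
    sub <- igraph::induced_subgraph(g, current)
    comp <- igraph::components(sub)
    memb <- stats::setNames(comp$membership,
                            igraph::V(sub)$name)
    keep_comps <- unique(memb[keep])
    if (length(keep_comps) <= 1 || length(added) >= max_extra) break

    candidates <- setdiff(spnw$nodes$id, current)
    if (length(candidates) == 0) break
    joins <- vapply(candidates, function(c0) {
      nb <- igraph::neighbors(g, c0)$name
      length(unique(memb[intersect(nb, current)][
        memb[intersect(nb, current)] %in% keep_comps
      ]))
    }, integer(1))
    best_join <- max(joins)
    if (best_join < 2) {
      dg_warn(sprintf(
        "Compact network left with %d separate components: no single connector joins two.",
        length(keep_comps)
      ))
      break
    }
    pool <- candidates[joins == best_join]
    pool <- pool[order(-spnw_deg[pool], pool)]
    pick <- pool[1]
    current <- c(current, pick)
    added <- c(added, pick)
  }

  nodes <- filter(spnw$nodes, .data$id %in% current)
  edges <- filter(spnw$edges,
                  .data$source %in% current & .data$target %in% current)
  dg_network(nodes, edges, name = "compact")
}
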