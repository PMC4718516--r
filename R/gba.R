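# Guilt-by-association: four-way node categorization against a known
# disease-gene list, first-level known-neighbor counts, an empirical
# permutation null, and the multi-evidence candidate report.

#' Categorize network nodes against a known-gene list
#'
#' Gene nodes fall into four exhaustive, mutually exclusive categories from
#' role (seed vs connector) crossed with known-list membership:
#' `known_sdeg`, `interest_sdeg`, `known_connector`, `interest_connector`.
#' miRNA nodes are excluded.
#'
#' @param net A [dg_network()].
#' @param seeds A `seed_gene_set` or character vector (defines the seed
#'   role; nodes already carry roles, the seed list is used to re-derive
#'   them defensively).
#' @param known Character vector of known disease genes (nonempty).
#' @return Tibble with columns `node`, `role`, `known`, `category`.
#' @export
categorize_nodes <- function(net, seeds, known) {
  known <- unique(norm_gene_id(known))
  if (length(known) == 0) dg_stop("Known-gene list is empty.")
  sd <- seed_ids(seeds)
  out <- filter(net$nodes, .data$role != "miRNA")
  out <- mutate(
    rename(out, node = "id"),
    role = ifelse(.data$node %in% sd, "seed", "connector"),
    known = .data$node %in% known,
    category = dplyr::case_when(
      .data$role == "seed" & .data$known ~ "known_sdeg",
      .data$role == "seed" ~ "interest_sdeg",
      .data$known ~ "known_connector",
      TRUE ~ "interest_connector"
    )
  )
  arrange(out, .data$node)
}

# Named list: node id -> character vector of neighbor ids (undirected
# simple view).
neighbor_map <- function(net) {
  g <- net_igraph(net)
  nb <- igraph::as_adj_list(g, mode = "all")
  ids <- igraph::V(g)$name
  stats::setNames(lapply(nb, function(v) ids[as.integer(v)]), ids)
}

#' First-level known-neighbor counts (guilt by association)
#'
#' For every candidate node, counts its first-level neighbors that are on
#' the known-gene list, on the undirected view; the neighbor ids themselves
#' are kept for auditability. A separate `known_within_2` flag records
#' second-level evidence (a known gene within distance 2) without mixing it
#' into the primary count.
#'
#' @param net A [dg_network()].
#' @param candidates Node ids to score (must be network nodes).
#' @param known Known disease genes.
#' @return Tibble sorted by descending `known_neighbor_count` (ties
#'   lexicographic): `node`, `known_neighbor_count`, `known_neighbors`
#'   (comma-separated), `known_within_2`.
#' @export
gba_counts <- function(net, candidates, known) {
  candidates <- unique(norm_gene_id(candidates))
  stray <- setdiff(candidates, net$nodes$id)
  if (length(stray) > 0) {
    dg_stop(sprintf("Candidate(s) outside the network: %s",
                    paste(head(stray, 3), collapse = ", ")))
  }
  known <- unique(norm_gene_id(known))
  nbm <- neighbor_map(net)
  rows <- purrr::map_dfr(candidates, function(cd) {
    nb <- nbm[[cd]] %||% character(0)
    hits <- sort(intersect(nb, known))
    second <- unique(unlist(nbm[nb], use.names = FALSE))
    tibble(
      node = cd,
      known_neighbor_count = length(hits),
      known_neighbors = paste(hits, collapse = ","),
      known_within_2 = length(hits) > 0 ||
        length(intersect(setdiff(second, cd), known)) > 0
    )
  })
  arrange(rows, desc(.data$known_neighbor_count), .data$node)
}

#' Permutation p-value for a candidate's known-neighbor count
#'
#' The empirical null permutes the known-label assignment uniformly over
#' the non-candidate gene nodes, keeping the graph fixed, and recomputes the
#' candidate's known-neighbor count. `p = (1 + #{permuted >= observed}) /
#' (n_perm + 1)`, so p is never below `1/(n_perm + 1)`.
#'
#' @param net A [dg_network()].
#' @param candidate One node id.
#' @param known Known disease genes.
#' @param n_perm Number of permutations (>= 100).
#' @param rng_seed Integer seed.
#' @return A single p-value in (0, 1].
#' @export
gba_permutation_test <- function(net, candidate, known, n_perm = 1000,
                                 rng_seed = 42) {
  if (n_perm < 100) dg_stop("n_perm must be >= 100.")
  candidate <- norm_gene_id(candidate)
  known <- unique(norm_gene_id(known))
  nbm <- neighbor_map(net)
  nb <- nbm[[candidate]] %||% character(0)
  obs <- length(intersect(nb, known))
  if (obs == 0) return(1)
  pool <- setdiff(net$nodes$id[net$nodes$role != "miRNA"], candidate)
  n_lab <- min(length(intersect(known, pool)), length(pool))
  with_seed(rng_seed, {
    hits <- vapply(seq_len(n_perm), function(i) {
      lab <- sample(pool, n_lab)
      length(intersect(nb, lab)) >= obs
    }, logical(1))
    (1 + sum(hits)) / (n_perm + 1)
  })
}

#' Multi-evidence candidate prioritization
#'
#' Combines categorization, guilt-by-association counts and centrality
#' ranks into one report: candidates are the `interest_*` nodes with at
#' least `min_known_neighbors` known first-level neighbors, flagged for
#' membership in the top-`topk_centrality` list of each centrality metric,
#' and sorted by known-neighbor count (descending) then betweenness rank.
#'
#' @param categories Output of [categorize_nodes()].
#' @param gba_scores Output of [gba_counts()] covering the candidates.
#' @param centralities Output of [compute_centralities()] on the same
#'   network.
#' @param min_known_neighbors Minimum known-neighbor count to report.
#' @param topk_centrality Size of each top-centrality list.
#' @return Tibble: `node`, `category`, `known_neighbor_count`,
#'   `known_neighbors`, `known_within_2`, `degree`, `closeness`,
#'   `betweenness`, `top_degree`, `top_closeness`, `top_betweenness`.
#' @export
prioritize <- function(categories, gba_scores, centralities,
                       min_known_neighbors = 1, topk_centrality = 25) {
  interest <- filter(categories,
                     .data$category %in% c("interest_sdeg",
                                           "interest_connector"))
  tops <- lapply(c("degree", "closeness", "betweenness"), function(m) {
    top_nodes(centralities, m, k = topk_centrality)$node
  })
  names(tops) <- c("degree", "closeness", "betweenness")

  out <- inner_join(select(interest, "node", "category"),
                    gba_scores, by = "node")
  out <- filter(out, .data$known_neighbor_count >= min_known_neighbors)
  out <- left_join(
    out,
    select(centralities, "node", "degree", "closeness", "betweenness",
           "rank_betweenness"),
    by = "node"
  )
  out <- mutate(
    out,
    top_degree = .data$node %in% tops$degree,
    top_closeness = .data$node %in% tops$closeness,
    top_betweenness = .data$node %in% tops$betweenness
  )
  out <- arrange(out, desc(.data$known_neighbor_count),
                 .data$rank_betweenness, .data$node)
  select(out, -"rank_betweenness")
}
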