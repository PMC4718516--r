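# Node descriptors on the undirected simple view: degree, closeness
# (Wasserman-Faust component scaling) and betweenness (Brandes' dependency
# accumulation), plus summaries and top-k reports.

# Adjacency as a list of integer neighbor vectors, undirected simple view.
adj_list_int <- function(g) {
  lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
}

# Single-source BFS; returns integer distances (NA = unreachable).
bfs_dist <- function(adj, s) {
  n <- length(adj)
  dist <- rep(NA_integer_, n)
  dist[s] <- 0L
  queue <- s
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    for (w in adj[[v]]) {
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
  }
  dist
}

# Brandes' algorithm for shortest-path betweenness on an unweighted
# undirected graph; returns the raw pair-based scores (each unordered pair
# counted once).
brandes_betweenness <- function(adj) {
  n <- length(adj)
  cb <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n)
    sigma[s] <- 1
    dist <- rep(-1L, n)
    dist[s] <- 0L
    preds <- vector("list", n)
    order_popped <- integer(0)
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      order_popped <- c(order_popped, v)
      for (w in adj[[v]]) {
        if (dist[w] < 0) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_popped)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) cb[w] <- cb[w] + delta[w]
    }
  }
  cb / 2
}

#' Compute degree, closeness and betweenness for every node
#'
#' All three descriptors are computed on the undirected simple view of the
#' network (multi-edges and interaction types collapsed). Closeness uses
#' the Wasserman-Faust component scaling: within a component of size
#' `n_C`, closeness is `(n_C - 1) / sum(d)` scaled by `(n_C - 1) / (n - 1)`,
#' so small disconnected components cannot inflate their scores; isolated
#' nodes score 0. Betweenness uses Brandes' dependency accumulation,
#' normalized by `2 / ((n - 1)(n - 2))` (unnormalized, with a warning, when
#' the network has fewer than 3 nodes). Ranks are 1-based dense ranks per
#' metric.
#'
#' @param net A [dg_network()].
#' @return Tibble with columns `node`, `role`, `degree`, `closeness`,
#'   `betweenness`, `rank_degree`, `rank_closeness`, `rank_betweenness`,
#'   sorted by id.
#' @export
compute_centralities <- function(net) {
  if (nrow(net$nodes) == 0) dg_stop("Cannot score an empty network.")
  g <- net_igraph(net)
  n <- igraph::vcount(g)
  ids <- igraph::V(g)$name
  adj <- adj_list_int(g)

  degree <- unname(vapply(adj, length, integer(1)))

  dists <- vapply(seq_len(n), function(s) bfs_dist(adj, s),
                  integer(n))
  if (n == 1) dists <- matrix(dists, 1, 1)
  closeness <- vapply(seq_len(n), function(i) {
    d <- dists[, i]
    reach <- which(!is.na(d) & d > 0)
    n_c <- length(reach) + 1
    if (n_c < 2) return(0)
    (n_c - 1) / sum(d[reach]) * (n_c - 1) / max(n - 1, 1)
  }, numeric(1))

  btw <- brandes_betweenness(adj)
  if (n >= 3) {
    btw <- btw / ((n - 1) * (n - 2) / 2)
  } else {
    dg_warn("Fewer than 3 nodes: betweenness left unnormalized.")
  }

  out <- tibble(
    node = ids,
    degree = degree,
    closeness = closeness,
    betweenness = btw
  )
  out <- left_join(out, rename(net$nodes, node = "id"), by = "node")
  out <- mutate(
    out,
    rank_degree = dense_rank(desc(.data$degree)),
    rank_closeness = dense_rank(desc(.data$closeness)),
    rank_betweenness = dense_rank(desc(.data$betweenness))
  )
  arrange(
    select(out, "node", "role", "degree", "closeness", "betweenness",
           dplyr::starts_with("rank_")),
    .data$node
  )
}

#' Average node degree
#'
#' `2 |E| / |V|` on the undirected simple view.
#'
#' @param net A [dg_network()].
#' @return A single number.
#' @export
average_degree <- function(net) {
  if (nrow(net$nodes) == 0) dg_stop("Empty network.")
  g <- net_igraph(net)
  2 * igraph::ecount(g) / igraph::vcount(g)
}

#' Top nodes by a centrality metric
#'
#' Descending by the chosen metric with lexicographic tie-break on the node
#' id; either the first `k` rows or all nodes strictly above `threshold`.
#'
#' @param records Centrality tibble from [compute_centralities()].
#' @param metric `"degree"`, `"closeness"` or `"betweenness"`.
#' @param k Number of top nodes to keep.
#' @param threshold Keep nodes with metric strictly greater than this.
#' @return Filtered, ordered centrality tibble.
#' @export
top_nodes <- function(records, metric = c("degree", "closeness",
                                          "betweenness"),
                      k = NULL, threshold = NULL) {
  metric <- match.arg(metric)
  ord <- records[order(-records[[metric]], records$node), , drop = FALSE]
  if (!is.null(threshold)) {
    ord <- ord[ord[[metric]] > threshold, , drop = FALSE]
  }
  if (!is.null(k)) {
    ord <- head(ord, k)
  }
  ord
}
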