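# Independent oracles used across the suite. These deliberately avoid the
# package's own graph code: distances and shortest-path counts come from
# powers of the adjacency matrix (the number of length-d(u,v) walks between
# u and v equals the number of shortest paths).

# Symmetric 0/1 adjacency matrix of a dg_network, built straight from the
# edge tibble.
oracle_adjacency <- function(net) {
  ids <- sort(net$nodes$id)
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(nrow(net$edges))) {
    s <- net$edges$source[i]
    t <- net$edges$target[i]
    if (s != t) {
      A[s, t] <- 1
      A[t, s] <- 1
    }
  }
  A
}

# Pairwise distances and shortest-path counts via adjacency powers.
oracle_dist_sigma <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  S <- diag(1, n)
  Ak <- diag(1, n)
  for (k in seq_len(n)) {
    Ak <- Ak %*% A
    newly <- is.infinite(D) & Ak > 0
    if (!any(newly)) next
    D[newly] <- k
    S[newly] <- Ak[newly]
  }
  list(D = D, sigma = S)
}

# Exhaustive betweenness: for every pair, count shortest paths through each
# interior node. Returns raw pair-based scores in node-id order.
oracle_betweenness <- function(net, normalized = TRUE) {
  A <- oracle_adjacency(net)
  o <- oracle_dist_sigma(A)
  n <- nrow(A)
  btw <- numeric(n)
  if (n >= 3) {
    for (s in seq_len(n - 1)) {
      for (t in seq(s + 1, n)) {
        d <- o$D[s, t]
        if (!is.finite(d) || d < 2) next
        for (v in seq_len(n)) {
          if (v != s && v != t && o$D[s, v] + o$D[v, t] == d) {
            btw[v] <- btw[v] + o$sigma[s, v] * o$sigma[v, t] / o$sigma[s, t]
          }
        }
      }
    }
  }
  if (normalized && n >= 3) btw <- btw / ((n - 1) * (n - 2) / 2)
  stats::setNames(btw, rownames(A))
}

oracle_closeness <- function(net) {
  A <- oracle_adjacency(net)
  o <- oracle_dist_sigma(A)
  n <- nrow(A)
  cl <- vapply(seq_len(n), function(i) {
    d <- o$D[i, ]
    reach <- is.finite(d) & d > 0
    n_c <- sum(reach) + 1
    if (n_c < 2) return(0)
    (n_c - 1) / sum(d[reach]) * (n_c - 1) / max(n - 1, 1)
  }, numeric(1))
  stats::setNames(cl, rownames(A))
}

# Exact hypergeometric upper tail by direct summation of the pmf.
oracle_hyper_upper <- function(k, n, K, N) {
  if (k == 0) return(1)
  j <- seq(k, min(n, K))
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Independent step-up BH implementation.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(p[o] * m / seq(m, 1)))
  q[order(o)]
}

# Random G(n, p) graph as a dg_network (pure R).
random_net <- function(n, p, seed, role = "gene") {
  set.seed(seed)
  ids <- sprintf("N%03d", seq_len(n))
  pairs <- utils::combn(ids, 2)
  keep <- stats::runif(ncol(pairs)) < p
  dg_network(
    tibble::tibble(id = ids, role = role),
    tibble::tibble(
      source = pairs[1, keep], target = pairs[2, keep],
      type = "binding", directed = FALSE
    ),
    name = "random"
  )
}

# Tiny deterministic interaction database used by several unit tests.
toy_db <- function() {
  interaction_db(tibble::tribble(
    ~source, ~target, ~type, ~directed,
    "A", "B", "binding", FALSE,
    "B", "C", "binding", FALSE,
    "C", "D", "direct regulation", TRUE,
    "A", "D", "protein modification", FALSE,
    "D", "E", "binding", FALSE,
    "M1", "A", "miRNA regulation", TRUE,
    "M1", "B", "miRNA regulation", TRUE,
    "M2", "E", "miRNA regulation", TRUE
  ))
}
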