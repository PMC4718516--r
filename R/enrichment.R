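# Local gene-set over-representation: hypergeometric upper-tail p-values,
# fold enrichment, Benjamini-Hochberg adjustment, and the per-collection
# enrichment table.

#' Hypergeometric upper-tail probability
#'
#' `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`: the chance of drawing at
#' least `k` annotated genes when `n` genes are drawn without replacement
#' from a universe of `N` containing `K` annotated ones. Evaluated through
#' the distribution's log-space tail for numerical stability.
#'
#' @param k Observed overlap (`0 <= k <= min(n, K)`).
#' @param n Query size.
#' @param K Set size in the background.
#' @param N Background size.
#' @return Upper-tail probability.
#' @export
hypergeom_upper_tail <- function(k, n, K, N) {
  if (any(k < 0) || any(n > N) || any(K > N) || any(k > pmin(n, K))) {
    dg_stop("Impossible hypergeometric configuration (need k <= min(n, K); n, K <= N).")
  }
  ifelse(k == 0, 1,
         exp(phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)))
}

#' Fold enrichment
#'
#' `(k/n) / (K/N)`: the query's annotation rate over the background rate;
#' defined as 0 when the overlap is empty.
#'
#' @inheritParams hypergeom_upper_tail
#' @return Fold-enrichment score.
#' @export
fold_enrichment <- function(k, n, K, N) {
  if (any(n <= 0) || any(K <= 0) || any(N <= 0)) {
    dg_stop("n, K and N must be positive.")
  }
  ifelse(k == 0, 0, (k / n) / (K / N))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control; adjusted values are returned in
#' input order and clipped at 1.
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    dg_stop("p-values must lie in [0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

#' Gene-set over-representation analysis
#'
#' Tests every set in a collection for over-representation in a query gene
#' list against a background universe, with the hypergeometric upper tail
#' and Benjamini-Hochberg correction. Sets are intersected with the
#' background first; sets smaller than `min_set_size` after intersection
#' are skipped (with a message). The background defaults to the caller's
#' universe choice — fold-enrichment values are only comparable for a fixed
#' background.
#'
#' @param query Gene ids (must be a subset of the background).
#' @param collection Gene-set tibble as from [read_gmt()] or
#'   [generate_pathways()], or a named list of character vectors.
#' @param background Character vector: the gene universe.
#' @param alpha Significance threshold on the adjusted p-value.
#' @param min_set_size Minimum post-intersection set size tested.
#' @return Tibble sorted by `p_adj` then descending fold: `name`, `k`, `n`,
#'   `K`, `N`, `fold`, `p_raw`, `p_adj`, `significant`, `genes`
#'   (comma-separated overlap).
#' @export
enrich <- function(query, collection, background, alpha = 0.05,
                   min_set_size = 3) {
  background <- unique(norm_gene_id(background))
  if (length(background) == 0) dg_stop("Background universe is empty.")
  query <- unique(norm_gene_id(query))
  outside <- setdiff(query, background)
  if (length(outside) > 0) {
    dg_stop(sprintf("%d query gene(s) outside the background (e.g. %s).",
                    length(outside), paste(head(outside, 3), collapse = ", ")))
  }
  if (!is.data.frame(collection)) {
    collection <- tibble(
      name = names(collection),
      description = "",
      genes = lapply(collection, norm_gene_id)
    )
  }

  N <- length(background)
  n <- length(query)
  rows <- purrr::map_dfr(seq_len(nrow(collection)), function(i) {
    members <- intersect(unique(norm_gene_id(collection$genes[[i]])),
                         background)
    K <- length(members)
    if (K < min_set_size) return(NULL)
    overlap <- sort(intersect(query, members))
    k <- length(overlap)
    tibble(
      name = collection$name[i],
      k = k, n = n, K = K, N = N,
      fold = fold_enrichment(k, n, K, N),
      p_raw = hypergeom_upper_tail(k, n, K, N),
      genes = paste(overlap, collapse = ",")
    )
  })
  skipped <- nrow(collection) - nrow(rows)
  if (skipped > 0) {
    inform(sprintf(
      "Skipped %d set(s) smaller than %d after background intersection.",
      skipped, min_set_size
    ))
  }
  if (nrow(rows) == 0) {
    return(tibble(name = character(), k = integer(), n = integer(),
                  K = integer(), N = integer(), fold = numeric(),
                  p_raw = numeric(), p_adj = numeric(),
                  significant = logical(), genes = character()))
  }
  rows <- mutate(rows,
                 p_adj = bh_adjust(.data$p_raw),
                 significant = .data$p_adj < alpha)
  select(
    arrange(rows, .data$p_adj, desc(.data$fold), .data$name),
    "name", "k", "n", "K", "N", "fold", "p_raw", "p_adj", "significant",
    "genes"
  )
}
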