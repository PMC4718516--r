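# Seed-gene selection: two-tier thresholding of per-contrast moderated
# statistics, Venn bookkeeping across contrasts, and the cross-study union
# that anchors all network construction.

stats_table <- function(stats) {
  if (inherits(stats, "moderated_stats")) return(stats$table)
  stats <- as_tibble(stats)
  stopifnot(all(c("gene", "p") %in% names(stats)))
  stats
}

#' Select significantly differentially expressed genes
#'
#' Genes with a contrast p-value strictly below `alpha`. The inequality is
#' strict, so a p-value exactly at the threshold does not qualify.
#'
#' @param stats A `moderated_stats` object or tibble with columns `gene`,
#'   `p`.
#' @param alpha Threshold in (0, 1].
#' @return Sorted character vector of gene ids.
#' @export
select_sdegs <- function(stats, alpha = 0.05) {
  if (alpha <= 0 || alpha > 1) dg_stop("alpha must lie in (0, 1].")
  tab <- stats_table(stats)
  sort(norm_gene_id(tab$gene[tab$p < alpha]))
}

#' Venn-region bookkeeping over 2-4 gene sets
#'
#' Computes all `2^k - 1` region cardinalities by inclusion membership
#' pattern, the full k-way intersection, and the union of all multi-set
#' regions (genes shared by at least two sets) — the two readings of a
#' multi-set "overlap".
#'
#' @param sets Named list of 2-4 character vectors.
#' @return List with tibble `$regions` (`pattern`, `sets`, `count`), and
#'   vectors `$intersection`, `$shared` (in >= 2 sets), `$union`.
#' @export
venn_regions <- function(sets) {
  k <- length(sets)
  if (k < 2 || k > 4) dg_stop("venn_regions needs 2-4 sets.")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- paste0("S", seq_len(k))
  }
  sets <- lapply(sets, function(s) unique(norm_gene_id(s)))
  all_genes <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) all_genes %in% s,
                   logical(length(all_genes)))
  member <- matrix(member, ncol = k,
                   dimnames = list(all_genes, names(sets)))
  gene_pattern <- apply(member, 1,
                        function(r) paste(as.integer(r), collapse = ""))

  grid <- expand.grid(rep(list(c(0L, 1L)), k))[-1, , drop = FALSE]
  names(grid) <- names(sets)
  pats <- apply(grid, 1, paste, collapse = "")
  regions <- tibble(
    pattern = pats,
    sets = apply(grid, 1, function(r) {
      paste(names(sets)[r == 1], collapse = "&")
    }),
    count = unname(vapply(pats, function(p) sum(gene_pattern == p),
                          integer(1)))
  )
  n_member <- rowSums(member)
  list(
    regions = arrange(regions, desc(nchar(gsub("0", "", .data$pattern))),
                      .data$pattern),
    intersection = all_genes[n_member == k],
    shared = all_genes[n_member >= 2],
    union = all_genes
  )
}

#' Union of per-study gene sets
#'
#' Combines SDEG lists across studies with duplicate removal after
#' identifier normalization.
#'
#' @param per_study_sets List of >= 1 character vectors.
#' @return Sorted character vector.
#' @export
combine_studies <- function(per_study_sets) {
  if (length(per_study_sets) < 1) dg_stop("Need at least one set.")
  sort(unique(norm_gene_id(unlist(per_study_sets))))
}

#' Final seed-gene set across all contrasts
#'
#' A gene becomes a seed by passing `p < alpha_final` in any contrast of any
#' study; the per-gene provenance records which contrasts it passed in. This
#' is the stricter tier anchoring network construction, below the looser
#' SDEG threshold.
#'
#' @param all_stats Named list of `moderated_stats` (or a nested list of
#'   such lists, one per study).
#' @param alpha_final Strict threshold for seed membership.
#' @return Object of class `seed_gene_set`: list with sorted `$genes`,
#'   `$tier`, and tibble `$provenance` (`gene`, `contrast`, `p`).
#' @export
final_seeds <- function(all_stats, alpha_final = 0.01) {
  flat <- list()
  for (nm in names(all_stats)) {
    el <- all_stats[[nm]]
    if (inherits(el, "moderated_stats")) {
      flat[[nm]] <- el
    } else {
      for (sub in names(el)) flat[[paste(nm, sub, sep = ".")]] <- el[[sub]]
    }
  }
  prov <- purrr::map_dfr(names(flat), function(nm) {
    tab <- stats_table(flat[[nm]])
    tab <- tab[tab$p < alpha_final, c("gene", "p")]
    if (nrow(tab) == 0) return(NULL)
    tibble(gene = norm_gene_id(tab$gene), contrast = nm, p = tab$p)
  })
  if (nrow(prov) == 0) {
    prov <- tibble(gene = character(), contrast = character(),
                   p = numeric())
  }
  genes <- sort(unique(prov$gene))
  if (length(genes) == 0) {
    dg_warn(sprintf(
      "No gene passed p < %g in any contrast; the seed set is empty.",
      alpha_final
    ))
  }
  structure(
    list(genes = genes, tier = alpha_final,
         provenance = arrange(prov, .data$gene, .data$contrast)),
    class = "seed_gene_set"
  )
}

#' @export
print.seed_gene_set <- function(x, ...) {
  cat(sprintf("<seed_gene_set> %d genes at p < %g (from %d contrast hits)\n",
              length(x$genes), x$tier, nrow(x$provenance)))
  invisible(x)
}

seed_ids <- function(seeds) {
  if (inherits(seeds, "seed_gene_set")) seeds$genes
  else sort(unique(norm_gene_id(seeds)))
}
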