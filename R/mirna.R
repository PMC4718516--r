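# miRNA regulatory overlay: miRNAs targeting a queried gene set, the
# known/novel split, the bipartite miRNA + transcription-factor regulatory
# network over seed genes, and hub-miRNA identification.

#' miRNAs targeting a gene set
#'
#' All miRNA nodes with at least one "miRNA regulation" edge into the query
#' genes. Reports the per-gene regulator lists and per-miRNA target counts
#' within the query; miRNAs hitting more than one query gene are flagged
#' multi-target.
#'
#' @param genes Query gene ids (nonempty).
#' @param db An [interaction_db()].
#' @return Object of class `mirna_report`: list with tibbles
#'   `$target_map` (`gene`, `mirnas`, `n_mirnas`), `$mirna_counts`
#'   (`mirna`, `n_targets`, `targets`, `multi_target`) and vector
#'   `$mirna_set`.
#' @export
mirnas_targeting <- function(genes, db) {
  genes <- unique(norm_gene_id(genes))
  if (length(genes) == 0) dg_stop("Query gene set is empty.")
  hits <- filter(db$edges,
                 .data$type == "miRNA regulation" &
                   .data$target %in% genes)
  target_map <- purrr::map_dfr(sort(genes), function(g) {
    m <- sort(unique(hits$source[hits$target == g]))
    tibble(gene = g, mirnas = paste(m, collapse = ","),
           n_mirnas = length(m))
  })
  mirna_counts <- summarise(
    group_by(distinct(hits, .data$source, .data$target), .data$source),
    n_targets = n(),
    targets = paste(sort(.data$target), collapse = ","),
    .groups = "drop"
  )
  mirna_counts <- arrange(
    mutate(rename(mirna_counts, mirna = "source"),
           multi_target = .data$n_targets > 1),
    desc(.data$n_targets), .data$mirna
  )
  structure(list(
    target_map = target_map,
    mirna_counts = mirna_counts,
    mirna_set = sort(unique(hits$source))
  ), class = "mirna_report")
}

#' @export
print.mirna_report <- function(x, ...) {
  cat(sprintf(
    "<mirna_report> %d miRNAs over %d queried genes (%d multi-target)\n",
    length(x$mirna_set), nrow(x$target_map),
    sum(x$mirna_counts$multi_target)
  ))
  invisible(x)
}

#' Split miRNAs into known and novel
#'
#' Partitions a miRNA set by membership in a known-disease-miRNA list.
#' Both sides are normalized with [norm_mirna_id()] first, so dialect
#' variants of the same name ("miR-29b-1" vs "miR-29b1") compare equal.
#'
#' @param mirna_set Character vector of miRNA ids.
#' @param known_mirnas Known-disease miRNA list.
#' @return List with sorted `$known` and `$novel` (normalized ids;
#'   disjoint, union = the normalized input set).
#' @export
classify_mirnas <- function(mirna_set, known_mirnas) {
  set <- unique(norm_mirna_id(mirna_set))
  known <- unique(norm_mirna_id(known_mirnas))
  list(
    known = sort(intersect(set, known)),
    novel = sort(setdiff(set, known))
  )
}

#' miRNA + transcription-factor regulatory network over seeds
#'
#' The bipartite overlay of gene-expression regulation on the seed set:
#' every "miRNA regulation" edge from the database into a seed gene, plus
#' every "promoter binding" / "expression" edge whose source is a
#' TF-flagged seed and whose target is a seed. Node roles are `miRNA` and
#' `gene`; the TF flag is carried in the node table.
#'
#' @param seeds A `seed_gene_set` or character vector.
#' @param db An [interaction_db()].
#' @param annotations Annotation tibble providing the `tf` flag.
#' @return A [dg_network()] whose node table has a `tf` column.
#' @export
mirna_regulatory_network <- function(seeds, db, annotations = NULL) {
  sd <- seed_ids(seeds)
  if (length(sd) == 0) dg_stop("Seed set is empty.")
  mir_edges <- filter(db$edges,
                      .data$type == "miRNA regulation" &
                        .data$target %in% sd)
  tf_genes <- character(0)
  if (!is.null(annotations)) {
    annotations <- validate_annotations(annotations)
    tf_genes <- annotations$id[annotations$tf]
  }
  tf_edges <- filter(db$edges,
                     .data$type %in% c("promoter binding", "expression") &
                       .data$source %in% intersect(sd, tf_genes) &
                       .data$target %in% sd)
  edges <- bind_rows(mir_edges, tf_edges)
  if (nrow(edges) == 0) {
    dg_warn("No regulatory edge into the seed set; the network is empty.")
    return(dg_network(tibble(id = character(), role = character()),
                      edges, name = "mirna_regulatory"))
  }
  ids <- sort(unique(c(edges$source, edges$target)))
  kind <- stats::setNames(db$nodes$kind, db$nodes$id)
  nodes <- tibble(
    id = ids,
    role = ifelse(kind[ids] == "miRNA", "miRNA", "gene"),
    tf = ids %in% tf_genes
  )
  dg_network(nodes, edges, name = "mirna_regulatory")
}

#' Hub miRNAs of a regulatory network
#'
#' Ranks the miRNA nodes by (degree, closeness, betweenness),
#' lexicographically, on the undirected view of the full bipartite network;
#' each miRNA's regulated genes are attached.
#'
#' @param net Network from [mirna_regulatory_network()].
#' @return Tibble `mirna`, `degree`, `closeness`, `betweenness`,
#'   `targets`, best-ranked first.
#' @export
hub_mirna <- function(net) {
  mirs <- net$nodes$id[net$nodes$role == "miRNA"]
  if (length(mirs) == 0) dg_stop("The network has no miRNA node.")
  cent <- suppressWarnings(compute_centralities(net))
  cent <- filter(rename(cent, mirna = "node"), .data$mirna %in% mirs)
  targets <- vapply(cent$mirna, function(m) {
    paste(sort(unique(net$edges$target[net$edges$source == m])),
          collapse = ",")
  }, "")
  out <- mutate(select(cent, "mirna", "degree", "closeness", "betweenness"),
                targets = unname(targets))
  arrange(out, desc(.data$degree), desc(.data$closeness),
          desc(.data$betweenness), .data$mirna)
}
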