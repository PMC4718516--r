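# Integrated mechanism network: consolidation of overlapping enriched
# pathway memberships, the typed induced subgraph over the consolidated
# genes, extracellular entry-node detection and harmful/protective
# bookkeeping.

#' Consolidate pathway gene lists
#'
#' The deduplicated union of the member genes of the selected pathways,
#' identifier-normalized and sorted. Idempotent and order-invariant; the
#' union size equals the sum of set sizes exactly when the sets are
#' pairwise disjoint.
#'
#' @param selected Gene-set tibble (as from [read_gmt()]) or list of
#'   character vectors.
#' @return Sorted character vector of unique genes.
#' @export
consolidate_pathway_genes <- function(selected) {
  if (is.data.frame(selected)) selected <- selected$genes
  if (length(selected) < 1) dg_stop("Need at least one pathway set.")
  genes <- sort(unique(norm_gene_id(unlist(selected))))
  if (length(genes) == 0) dg_stop("The pathway union is empty.")
  genes
}

#' Build the mechanism network over consolidated genes
#'
#' The typed subgraph of the interaction database induced on the
#' consolidated gene list, retaining edge direction and type. Genes absent
#' from the database or without induced interactions are kept as isolated
#' nodes: the mechanism gene list is fixed by the pathway consolidation,
#' not by connectivity.
#'
#' @param genes Consolidated gene list (>= 2 present in the database).
#' @param db An [interaction_db()].
#' @return A [dg_network()] (role `gene`), with attribute `absent` listing
#'   genes not found in the database.
#' @export
build_mechanism_network <- function(genes, db) {
  genes <- sort(unique(norm_gene_id(genes)))
  present <- intersect(genes, db$nodes$id)
  if (length(present) < 2) {
    dg_stop(sprintf(
      "Only %d of %d mechanism genes occur in the database; need >= 2.",
      length(present), length(genes)
    ))
  }
  net <- dg_network(
    tibble(id = present, role = "gene"),
    induced_edges(db, present),
    name = "mechanism"
  )
  attr(net, "absent") <- setdiff(genes, present)
  net
}

#' Detect extracellular entry nodes
#'
#' Entry nodes model routes of disease initiation from outside the cell:
#' genes annotated extracellular that have at least one edge (any
#' direction) to a non-extracellular mechanism gene. Sorted by out-degree
#' within the mechanism network, then id. Genes without annotation count as
#' localization "unknown" and can never qualify.
#'
#' @param mech Mechanism network from [build_mechanism_network()].
#' @param annotations Annotation tibble (see [read_annotations()]).
#' @return Tibble `node`, `out_degree`, `partners` (non-extracellular
#'   mechanism neighbors, comma-separated).
#' @export
detect_entry_nodes <- function(mech, annotations) {
  annotations <- validate_annotations(annotations)
  loc <- stats::setNames(annotations$localization, annotations$id)
  ids <- mech$nodes$id
  extracell <- ids[!is.na(loc[ids]) & loc[ids] == "extracellular"]
  if (length(extracell) == 0) {
    dg_warn("No extracellular gene in the mechanism network.")
    return(tibble(node = character(), out_degree = integer(),
                  partners = character()))
  }
  nbm <- neighbor_map(mech)
  out_deg <- vapply(ids, function(v) {
    sum(mech$edges$source == v & mech$edges$directed)
  }, integer(1))
  rows <- purrr::map_dfr(extracell, function(v) {
    nb <- nbm[[v]] %||% character(0)
    inward <- sort(nb[is.na(loc[nb]) | loc[nb] != "extracellular"])
    if (length(inward) == 0) return(NULL)
    tibble(node = v, out_degree = out_deg[[v]],
           partners = paste(inward, collapse = ","))
  })
  arrange(rows, desc(.data$out_degree), .data$node)
}

#' Harmful/protective bookkeeping for mechanism genes
#'
#' Copies each mechanism gene's effect label from the annotations
#' (unannotated genes become "unknown") and reports the label fractions.
#' With `known_only = TRUE` the harmful/protective fractions are taken over
#' labelled genes only.
#'
#' @param mech Mechanism network.
#' @param annotations Annotation tibble.
#' @param known_only Exclude "unknown" genes from the fraction denominator.
#' @return List with tibble `$labels` (`node`, `effect`) and tibble
#'   `$summary` (`effect`, `count`, `fraction`).
#' @export
label_effects <- function(mech, annotations, known_only = FALSE) {
  annotations <- validate_annotations(annotations)
  eff <- stats::setNames(annotations$effect, annotations$id)
  labels <- tibble(
    node = mech$nodes$id,
    effect = dplyr::coalesce(unname(eff[mech$nodes$id]), "unknown")
  )
  denom_tbl <- if (known_only) {
    filter(labels, .data$effect != "unknown")
  } else {
    labels
  }
  summary <- count(labels, .data$effect, name = "count")
  summary <- mutate(summary,
                    fraction = .data$count / max(nrow(denom_tbl), 1))
  if (known_only) {
    summary <- filter(summary, .data$effect != "unknown")
  }
  list(labels = labels, summary = arrange(summary, desc(.data$count)))
}
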