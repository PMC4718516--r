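# Curated inputs shipped with the package: the twelve enriched KEGG
# pathway memberships reported for Alzheimer's disease, the known and
# candidate therapeutic miRNA lists, and a synthetic miRNA-to-key-gene
# wiring for demonstration runs.

dg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "dgnet")
  if (!nzchar(path)) dg_stop(sprintf("Bundled file '%s' not found.", file))
  path
}

#' Curated Alzheimer's disease pathway collection
#'
#' The twelve enriched KEGG pathway memberships reported for the disease
#' (ALS, chemokine signaling, neurotrophin signaling, Alzheimer's disease,
#' NK-cell cytotoxicity, long-term potentiation, T/B-cell receptor
#' signaling, adherens junction, calcium signaling, ErbB and TGF-beta
#' signaling), shipped in GMT layout. Their consolidated union is the
#' 37-gene mechanism list.
#'
#' @return Gene-set tibble (see [read_gmt()]).
#' @export
ad_pathways <- function() {
  read_gmt(dg_extdata("ad_kegg_pathways.gmt"))
}

#' Curated Alzheimer's disease miRNA lists
#'
#' `ad_known_mirnas()` returns the five miRNAs already associated with the
#' disease; `ad_novel_mirnas()` the seventeen proposed candidate
#' therapeutic miRNAs. Ids are normalized with [norm_mirna_id()].
#'
#' @return Character vector of normalized miRNA ids.
#' @export
ad_known_mirnas <- function() {
  read_id_list(dg_extdata("ad_known_mirnas.txt"), mirna = TRUE)
}

#' @rdname ad_known_mirnas
#' @export
ad_novel_mirnas <- function() {
  read_id_list(dg_extdata("ad_novel_mirnas.txt"), mirna = TRUE)
}

#' Synthetic miRNA-to-key-gene interaction database
#'
#' A small demonstration database wiring the 22 curated miRNAs to the six
#' key genes (APP, BACE1, PSEN1, CD4, DCN, IL8). The per-gene regulator
#' counts follow the reported bookkeeping, but the individual pairings are
#' synthetic: the real curated pairings are proprietary and are not
#' reproduced here.
#'
#' @return An [interaction_db()].
#' @export
synthetic_mirna_target_db <- function() {
  read_edges(dg_extdata("synthetic_mirna_targets.tsv"))
}
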