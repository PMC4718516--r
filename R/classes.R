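# Core containers: typed interaction database, expression study, network.

#' Construct a typed interaction database
#'
#' The interaction database is the universe for all network construction: a
#' set of typed, optionally directed edges over gene and miRNA nodes. On
#' construction the edge set is canonicalized: identifiers are uppercased,
#' self-loops are dropped (with a warning giving the count), duplicate
#' (source, target, type) triples are collapsed, and undirected edges are
#' stored with the lexicographically smaller endpoint first so writers are
#' deterministic.
#'
#' @param edges Data frame with columns `source`, `target`, `type` and
#'   optionally `directed` (logical). When `directed` is absent, edges of
#'   type "miRNA regulation", "promoter binding", "direct regulation" and
#'   "expression" default to directed, all others to undirected.
#' @param nodes Optional data frame with columns `id`, `kind`
#'   (`"gene"`/`"miRNA"`). When omitted, sources of "miRNA regulation" edges
#'   are classified as miRNA nodes and every other endpoint as a gene.
#' @param lenient If `TRUE`, unknown edge types are kept; otherwise they are
#'   an error.
#' @return An object of class `interaction_db` with tibbles `$edges` and
#'   `$nodes`.
#' @export
interaction_db <- function(edges, nodes = NULL, lenient = FALSE) {
  edges <- as_tibble(edges)
  stopifnot(all(c("source", "target", "type") %in% names(edges)))
  edges$source <- norm_gene_id(edges$source)
  edges$target <- norm_gene_id(edges$target)
  edges$type <- as.character(edges$type)

  bad_type <- setdiff(unique(edges$type), edge_types())
  if (length(bad_type) > 0 && !lenient) {
    dg_stop(c(
      "Unknown interaction type(s) in edge table:",
      stats::setNames(bad_type, rep("x", length(bad_type))),
      i = "Use `lenient = TRUE` to keep them."
    ))
  }

  if (!"directed" %in% names(edges)) {
    edges$directed <- edges$type %in%
      c("miRNA regulation", "promoter binding", "direct regulation",
        "expression")
  }
  edges$directed <- as.logical(edges$directed)

  loops <- edges$source == edges$target
  if (any(loops)) {
    dg_warn(sprintf("Dropped %d self-loop edge(s).", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }

  # canonical orientation for undirected edges
  flip <- !edges$directed & edges$source > edges$target
  if (any(flip)) {
    tmp <- edges$source[flip]
    edges$source[flip] <- edges$target[flip]
    edges$target[flip] <- tmp
  }
  edges <- distinct(edges, .data$source, .data$target, .data$type,
                    .keep_all = TRUE)
  edges <- arrange(edges, .data$source, .data$target, .data$type)

  ids <- unique(c(edges$source, edges$target))
  if (is.null(nodes)) {
    mir <- unique(edges$source[edges$type == "miRNA regulation"])
    nodes <- tibble(id = sort(ids),
                    kind = ifelse(sort(ids) %in% mir, "miRNA", "gene"))
  } else {
    nodes <- as_tibble(nodes)
    stopifnot(all(c("id", "kind") %in% names(nodes)))
    nodes$id <- norm_gene_id(nodes$id)
    nodes <- distinct(arrange(nodes, .data$id))
    missing <- setdiff(ids, nodes$id)
    if (length(missing) > 0) {
      dg_stop(sprintf(
        "%d edge endpoint(s) have no node annotation (e.g. %s).",
        length(missing), paste(head(missing, 3), collapse = ", ")
      ))
    }
  }
  if (!all(nodes$kind %in% c("gene", "miRNA"))) {
    dg_stop("Node kind must be 'gene' or 'miRNA'.")
  }

  mir_nodes <- nodes$id[nodes$kind == "miRNA"]
  bad_src <- edges$type == "miRNA regulation" & !(edges$source %in% mir_nodes)
  if (any(bad_src)) {
    dg_stop(sprintf(
      "%d 'miRNA regulation' edge(s) originate from non-miRNA nodes.",
      sum(bad_src)
    ))
  }
  prot_types <- setdiff(edge_types(), "miRNA regulation")
  bad_mir <- (edges$type %in% prot_types) &
    (edges$source %in% mir_nodes | edges$target %in% mir_nodes)
  if (any(bad_mir)) {
    dg_stop(sprintf(
      "%d protein-type edge(s) touch miRNA nodes.", sum(bad_mir)
    ))
  }

  structure(list(edges = edges, nodes = nodes), class = "interaction_db")
}

#' @export
print.interaction_db <- function(x, ...) {
  cat(sprintf(
    "<interaction_db> %d nodes (%d genes, %d miRNAs), %d typed edges\n",
    nrow(x$nodes), sum(x$nodes$kind == "gene"),
    sum(x$nodes$kind == "miRNA"), nrow(x$edges)
  ))
  invisible(x)
}

#' Gene and miRNA node identifiers of a database
#'
#' @param db An `interaction_db`.
#' @return Character vector of node ids.
#' @export
db_genes <- function(db) db$nodes$id[db$nodes$kind == "gene"]

#' @rdname db_genes
#' @export
db_mirnas <- function(db) db$nodes$id[db$nodes$kind == "miRNA"]

# Undirected simple igraph view over all nodes (types and multiplicity
# collapsed); the view used for degrees, distances and centralities.
db_igraph <- function(db, nodes = db$nodes$id) {
  el <- db$edges[db$edges$source %in% nodes & db$edges$target %in% nodes,
                 c("source", "target")]
  g <- igraph::graph_from_data_frame(
    el, directed = FALSE,
    vertices = data.frame(name = nodes)
  )
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Construct an expression study
#'
#' Bundles a numeric expression matrix (rows are probes or genes, columns
#' samples, log2 scale after normalization) with its sample sheet. The sheet
#' must describe exactly the matrix columns, in order.
#'
#' @param values Numeric matrix with unique row names.
#' @param sample_sheet Data frame with columns `sample`,
#'   `condition` (`"case"`/`"control"`) and `stage`; an optional `pair`
#'   column marks paired designs.
#' @param name Study label.
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(values, sample_sheet, name = "study") {
  values <- as.matrix(values)
  if (!is.numeric(values)) dg_stop("Expression values must be numeric.")
  if (is.null(rownames(values))) dg_stop("Expression matrix needs row ids.")
  rownames(values) <- norm_gene_id(rownames(values))
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup) > 0) {
    dg_stop(sprintf("Duplicate row id(s): %s",
                    paste(head(dup, 5), collapse = ", ")))
  }
  if (anyNA(values)) dg_stop("Expression matrix contains missing values.")

  sample_sheet <- as_tibble(sample_sheet)
  stopifnot(all(c("sample", "condition", "stage") %in% names(sample_sheet)))
  sample_sheet$sample <- as.character(sample_sheet$sample)
  if (!all(sample_sheet$condition %in% c("case", "control"))) {
    dg_stop("Sample conditions must be 'case' or 'control'.")
  }
  miss_mat <- setdiff(sample_sheet$sample, colnames(values))
  miss_sheet <- setdiff(colnames(values), sample_sheet$sample)
  if (length(miss_mat) > 0 || length(miss_sheet) > 0) {
    dg_stop(c(
      "Sample sheet and matrix columns disagree.",
      if (length(miss_mat) > 0) {
        stats::setNames(paste("in sheet only:", paste(miss_mat, collapse = ", ")), "x")
      },
      if (length(miss_sheet) > 0) {
        stats::setNames(paste("in matrix only:", paste(miss_sheet, collapse = ", ")), "x")
      }
    ))
  }
  values <- values[, sample_sheet$sample, drop = FALSE]

  structure(list(values = values, sample_sheet = sample_sheet, name = name),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf(
    "<expression_study '%s'> %d features x %d samples (%d case / %d control; stages: %s)\n",
    x$name, nrow(x$values), ncol(x$values),
    sum(x$sample_sheet$condition == "case"),
    sum(x$sample_sheet$condition == "control"),
    paste(unique(x$sample_sheet$stage), collapse = ", ")
  ))
  invisible(x)
}

#' Construct a network result
#'
#' A constructed subnetwork: nodes with roles (`seed`, `connector`, `miRNA`,
#' `gene`), a typed edge subset of the parent interaction database, and a
#' label.
#'
#' @param nodes Data frame with columns `id`, `role`.
#' @param edges Data frame with columns `source`, `target`, `type`,
#'   `directed`.
#' @param name Network label.
#' @return An object of class `dg_network`.
#' @export
dg_network <- function(nodes, edges, name = "network") {
  nodes <- arrange(distinct(as_tibble(nodes)), .data$id)
  edges <- as_tibble(edges)
  stray <- setdiff(unique(c(edges$source, edges$target)), nodes$id)
  if (length(stray) > 0) {
    dg_stop(sprintf("Edge endpoint(s) outside node set: %s",
                    paste(head(stray, 3), collapse = ", ")))
  }
  edges <- arrange(edges, .data$source, .data$target, .data$type)
  structure(list(nodes = nodes, edges = edges, name = name),
            class = "dg_network")
}

#' @export
print.dg_network <- function(x, ...) {
  tab <- table(x$nodes$role)
  cat(sprintf(
    "<dg_network '%s'> %d nodes (%s), %d edges\n",
    x$name, nrow(x$nodes),
    paste(sprintf("%s: %d", names(tab), as.integer(tab)), collapse = ", "),
    nrow(x$edges)
  ))
  invisible(x)
}

# Undirected simple igraph view of a network (isolated nodes kept).
net_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("source", "target")],
    directed = FALSE,
    vertices = data.frame(name = net$nodes$id)
  )
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}
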