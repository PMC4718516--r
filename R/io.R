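# Readers and writers for every on-disk format the pipeline touches.
# All readers validate and reject rather than coerce; all writers emit
# deterministically ordered TSV so outputs are diffable.

#' Read an expression study from TSV
#'
#' @param matrix_path TSV with a header; first column holds row ids, the
#'   remaining columns one sample each.
#' @param sheet_path TSV sample sheet with columns `sample`, `condition`,
#'   `stage` (optionally `pair`).
#' @param name Study label (defaults to the matrix file name).
#' @return An [expression_study()].
#' @export
read_expression <- function(matrix_path, sheet_path,
                            name = basename(matrix_path)) {
  mat_df <- readr::read_tsv(matrix_path, col_types = readr::cols(),
                            progress = FALSE)
  ids <- as.character(mat_df[[1]])
  num <- mat_df[, -1, drop = FALSE]
  for (j in seq_along(num)) {
    col <- num[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1]
      dg_stop(sprintf(
        "Non-numeric expression value at row %d ('%s'), column '%s'.",
        bad, ids[bad], names(num)[j]
      ))
    }
  }
  values <- as.matrix(num)
  rownames(values) <- ids
  sheet <- readr::read_tsv(sheet_path, col_types = readr::cols(),
                           progress = FALSE)
  expression_study(values, sheet, name = name)
}

#' Write an expression study to TSV
#'
#' @param study An [expression_study()].
#' @param matrix_path,sheet_path Output file paths.
#' @return The study, invisibly.
#' @export
write_expression <- function(study, matrix_path, sheet_path) {
  df <- bind_cols(tibble(feature = rownames(study$values)),
                  as_tibble(study$values))
  readr::write_tsv(df, matrix_path, progress = FALSE)
  readr::write_tsv(study$sample_sheet, sheet_path, progress = FALSE)
  invisible(study)
}

#' Read a typed edge table
#'
#' Accepts the 3-column SIF-compatible dialect (`source  type  target`) or
#' the extended 4-column dialect (`source  target  type  directed`, with a
#' header row). Self-loop rows are dropped with a warning; unknown types are
#' an error unless `lenient = TRUE`.
#'
#' @param path Edge table TSV.
#' @param lenient Keep unknown interaction types instead of failing.
#' @return An [interaction_db()].
#' @export
read_edges <- function(path, lenient = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) dg_stop("Empty edge file.")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_f <- lengths(fields)
  header <- fields[[1]]
  if (identical(tolower(header[1]), "source")) {
    # 4-column dialect with header
    body <- fields[-1]
    bad <- which(lengths(body) < 3)
    if (length(bad) > 0) {
      dg_stop(sprintf("Malformed edge line %d (need >= 3 fields).",
                      bad[1] + 1L))
    }
    edges <- tibble(
      source = vapply(body, `[`, "", 1),
      target = vapply(body, `[`, "", 2),
      type = vapply(body, `[`, "", 3),
      directed = vapply(body, function(f) {
        if (length(f) >= 4) as.logical(f[4]) else NA
      }, NA)
    )
    if (anyNA(edges$directed)) edges$directed <- NULL
  } else {
    # SIF: source <TAB> type <TAB> target
    bad <- which(n_f != 3)
    if (length(bad) > 0) {
      dg_stop(sprintf("Malformed SIF line %d (need exactly 3 fields).",
                      bad[1]))
    }
    edges <- tibble(
      source = vapply(fields, `[`, "", 1),
      type = vapply(fields, `[`, "", 2),
      target = vapply(fields, `[`, "", 3)
    )
  }
  interaction_db(edges, lenient = lenient)
}

#' Write a typed edge table
#'
#' Emits the extended 4-column dialect with a header, in canonical order.
#'
#' @param db An [interaction_db()].
#' @param path Output path.
#' @return The database, invisibly.
#' @export
write_edges <- function(db, path) {
  readr::write_tsv(db$edges, path, progress = FALSE)
  invisible(db)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT layout: one set per line, tab-separated
#' `name  description  member1  member2 ...`. Member ids are
#' uppercase-normalized; duplicate set names and empty member lists are
#' errors.
#'
#' @param path GMT file.
#' @return A tibble with columns `name`, `description` and list-column
#'   `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    dg_stop(sprintf(
      "GMT line %d has fewer than 3 fields (a set needs >= 1 member).",
      short[1]
    ))
  }
  out <- tibble(
    name = vapply(fields, `[`, "", 1),
    description = vapply(fields, `[`, "", 2),
    genes = lapply(fields, function(f) unique(norm_gene_id(f[-(1:2)])))
  )
  dup <- unique(out$name[duplicated(out$name)])
  if (length(dup) > 0) {
    dg_stop(sprintf("Duplicate gene-set name(s): %s",
                    paste(dup, collapse = ", ")))
  }
  out
}

#' Write a GMT gene-set collection
#'
#' @param sets Tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return The collection, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$name[i], sets$description[i], sets$genes[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(sets)
}

#' Read / write a plain one-id-per-line list
#'
#' @param path File path.
#' @param mirna Normalize as miRNA ids instead of gene symbols.
#' @return Character vector of normalized ids.
#' @export
read_id_list <- function(path, mirna = FALSE) {
  x <- readLines(path)
  x <- x[nzchar(trimws(x))]
  if (mirna) norm_mirna_id(x) else norm_gene_id(x)
}

#' @rdname read_id_list
#' @param ids Character vector to write.
#' @export
write_id_list <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(ids)
}

#' Read / write node annotations
#'
#' Annotations carry a cellular localization (`extracellular`, `membrane`,
#' `cytoplasm`, `nucleus`), an effect label (`harmful`, `protective`,
#' `unknown`) and a transcription-factor flag per gene. Labels outside the
#' closed vocabularies are rejected.
#'
#' @param path Annotation TSV with columns `id`, `localization`, `effect`,
#'   `tf`.
#' @return Tibble of annotations.
#' @export
read_annotations <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  validate_annotations(ann)
}

#' @rdname read_annotations
#' @param ann Annotation tibble.
#' @export
write_annotations <- function(ann, path) {
  readr::write_tsv(arrange(ann, .data$id), path, progress = FALSE)
  invisible(ann)
}

validate_annotations <- function(ann) {
  ann <- as_tibble(ann)
  stopifnot(all(c("id", "localization", "effect") %in% names(ann)))
  ann$id <- norm_gene_id(ann$id)
  if (!"tf" %in% names(ann)) ann$tf <- FALSE
  ann$tf <- as.logical(ann$tf)
  if (!all(ann$localization %in%
           c("extracellular", "membrane", "cytoplasm", "nucleus"))) {
    dg_stop("Localization labels outside the closed vocabulary.")
  }
  if (!all(ann$effect %in% c("harmful", "protective", "unknown"))) {
    dg_stop("Effect labels outside the closed vocabulary.")
  }
  arrange(ann, .data$id)
}

#' Export a network to Pajek NET, GraphML or TSV
#'
#' Pajek NET uses 1-based vertex numbering with quoted labels, a `*Vertices`
#' section, then `*Edges` (undirected) and `*Arcs` (directed) sections.
#' GraphML (via igraph) carries node role attributes. TSV writes the typed
#' edge table in the 4-column dialect, re-readable with [read_edges()].
#'
#' @param net A [dg_network()].
#' @param path Output path.
#' @param format One of `"pajek_net"`, `"graphml"`, `"tsv"`.
#' @return The network, invisibly.
#' @export
export_network <- function(net, path, format = c("pajek_net", "graphml", "tsv")) {
  if (nrow(net$nodes) == 0) dg_stop("Cannot export an empty network.")
  format <- match.arg(format)
  if (format == "pajek_net") {
    ids <- net$nodes$id
    idx <- stats::setNames(seq_along(ids), ids)
    und <- net$edges[!net$edges$directed, , drop = FALSE]
    dir <- net$edges[net$edges$directed, , drop = FALSE]
    lines <- c(
      sprintf("*Vertices %d", length(ids)),
      sprintf('%d "%s"', seq_along(ids), ids),
      "*Edges",
      if (nrow(und) > 0) sprintf("%d %d", idx[und$source], idx[und$target]),
      "*Arcs",
      if (nrow(dir) > 0) sprintf("%d %d", idx[dir$source], idx[dir$target])
    )
    writeLines(lines, path)
  } else if (format == "graphml") {
    g <- igraph::graph_from_data_frame(
      net$edges, directed = TRUE,
      vertices = as.data.frame(net$nodes)
    )
    igraph::write_graph(g, path, format = "graphml")
  } else {
    readr::write_tsv(net$edges, path, progress = FALSE)
  }
  invisible(net)
}
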