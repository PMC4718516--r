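# Synthetic-data generators: a scale-free typed interactome with a planted
# disease module, multi-stage case/control expression studies with planted
# differential expression, module-biased pathway sets, node annotations and
# a miRNA-target map. Together these emulate the statistical structure the
# analysis assumes (literature-interactome degree skew, consistent
# dysregulation across disease stages, overlapping pathway membership), so
# the full pipeline can be run and validated without any download.

default_edge_type_weights <- function() {
  c(
    "binding" = 0.25,
    "chemical reaction" = 0.05,
    "direct regulation" = 0.15,
    "expression" = 0.15,
    "miRNA regulation" = 0.05,
    "molecular synthesis" = 0.05,
    "molecular transport" = 0.05,
    "promoter binding" = 0.10,
    "protein modification" = 0.15
  )
}

#' Generate a scale-free typed interactome
#'
#' The gene backbone is grown by preferential attachment (Barabasi-Albert),
#' which reproduces the pronounced hubs of curated literature interactomes.
#' miRNA nodes are attached afterwards, each wired to 1-10 distinct gene
#' targets with type "miRNA regulation"; miRNA nodes carry no protein-type
#' edges and receive no incoming edges from genes.
#'
#' @param n_genes Number of gene nodes (ids `G0001...`).
#' @param n_mirnas Number of miRNA nodes (ids `MIR0001...`).
#' @param m_attach Edges added per new gene during growth (`m_attach = 1`
#'   yields a tree).
#' @param edge_type_weights Named probabilities over the nine
#'   [edge_types()]; gene-gene edges draw from the non-miRNA types,
#'   renormalized.
#' @param directed_fraction Fraction of gene-gene edges marked directed
#'   (random orientation).
#' @param rng_seed Integer seed.
#' @return An [interaction_db()].
#' @export
generate_interactome <- function(n_genes,
                                 n_mirnas = 0,
                                 m_attach = 3,
                                 edge_type_weights = default_edge_type_weights(),
                                 directed_fraction = 0.3,
                                 rng_seed = 42) {
  if (m_attach < 1 || n_genes < m_attach) {
    dg_stop("Need n_genes >= m_attach >= 1.")
  }
  w <- edge_type_weights[edge_types()]
  if (anyNA(w) || any(w < 0) || sum(w) <= 0) {
    dg_stop("edge_type_weights must be nonnegative over the nine edge types.")
  }
  w <- w / sum(w)
  if (n_mirnas > 0 && w[["miRNA regulation"]] == 0) {
    dg_stop("n_mirnas > 0 requires positive weight on 'miRNA regulation'.")
  }

  with_seed(rng_seed, {
    gene_ids <- sprintf("G%04d", seq_len(n_genes))
    g <- igraph::sample_pa(n_genes, m = m_attach, directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    # collapse the multi-edges preferential attachment can produce
    el <- unique(cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))

    prot_w <- w[setdiff(edge_types(), "miRNA regulation")]
    prot_w <- prot_w / sum(prot_w)
    gene_edges <- tibble(
      source = gene_ids[el[, 1]],
      target = gene_ids[el[, 2]],
      type = sample(names(prot_w), nrow(el), replace = TRUE, prob = prot_w),
      directed = runif(nrow(el)) < directed_fraction
    )

    mirna_edges <- NULL
    nodes <- tibble(id = gene_ids, kind = "gene")
    if (n_mirnas > 0) {
      mir_ids <- sprintf("MIR%04d", seq_len(n_mirnas))
      mirna_edges <- purrr::map_dfr(mir_ids, function(m) {
        k <- sample.int(min(10L, n_genes), 1)
        tibble(source = m,
               target = sample(gene_ids, k),
               type = "miRNA regulation",
               directed = TRUE)
      })
      nodes <- bind_rows(nodes, tibble(id = mir_ids, kind = "miRNA"))
    }
    interaction_db(bind_rows(gene_edges, mirna_edges), nodes = nodes)
  })
}

#' Plant a disease module in an interactome
#'
#' Chooses a connected gene subset, densifies it by adding extra
#' within-module edges, and splits the members into "known" disease genes
#' and withheld "planted candidates" — the ground truth that
#' guilt-by-association recovery is judged against.
#'
#' @param db An [interaction_db()].
#' @param module_size Number of module genes (>= 2).
#' @param known_fraction Fraction labelled known
#'   (`ceiling(known_fraction * module_size)` members).
#' @param densification Probability of adding an edge for each absent
#'   within-module gene pair.
#' @param rng_seed Integer seed.
#' @return List with the densified `db`, `known_genes`,
#'   `planted_candidates` and the full `module` vector.
#' @export
plant_disease_module <- function(db, module_size, known_fraction = 0.5,
                                 densification = 0.2, rng_seed = 42) {
  if (module_size < 2) dg_stop("module_size must be >= 2.")
  genes <- db_genes(db)
  if (module_size > length(genes)) {
    dg_stop("module_size exceeds the gene count.")
  }
  if (known_fraction <= 0 || known_fraction >= 1) {
    dg_stop("known_fraction must lie strictly between 0 and 1.")
  }

  with_seed(rng_seed, {
    g <- db_igraph(db, nodes = genes)
    adj <- igraph::as_adj_list(g)
    names(adj) <- genes

    start <- sample(genes, 1)
    module <- start
    frontier <- setdiff(genes[unlist(adj[[start]])], module)
    while (length(module) < module_size) {
      if (length(frontier) == 0) {
        # disconnected gene graph fallback: restart from an unused gene
        frontier <- sample(setdiff(genes, module), 1)
      }
      nxt <- if (length(frontier) == 1) frontier else sample(frontier, 1)
      module <- c(module, nxt)
      frontier <- setdiff(
        unique(c(frontier, genes[unlist(adj[[nxt]])])), module
      )
    }
    module <- sort(module)

    pairs <- utils::combn(module, 2)
    existing <- paste(db$edges$source, db$edges$target)
    absent <- !(paste(pairs[1, ], pairs[2, ]) %in% existing |
                  paste(pairs[2, ], pairs[1, ]) %in% existing)
    add <- absent & (runif(ncol(pairs)) < densification)
    if (any(add)) {
      prot <- setdiff(edge_types(), "miRNA regulation")
      new_edges <- tibble(
        source = pairs[1, add],
        target = pairs[2, add],
        type = sample(prot, sum(add), replace = TRUE),
        directed = FALSE
      )
      db <- interaction_db(bind_rows(db$edges, new_edges), nodes = db$nodes)
    }

    n_known <- ceiling(known_fraction * module_size)
    known <- sort(sample(module, n_known))
    list(
      db = db,
      known_genes = known,
      planted_candidates = setdiff(module, known),
      module = module
    )
  })
}

#' Simulate a multi-stage case/control expression study
#'
#' Expression value = per-gene baseline + condition effect (+/- `effect_size`
#' for DE genes in case samples, with the sign drawn once per gene and held
#' fixed across stages, emulating consistent dysregulation as disease
#' progresses) + per-sample offset ~ N(0, `batch_shift`) + noise
#' ~ N(0, `sigma`). In a paired design the case and control member of a pair
#' share one offset, so paired contrasts gain power.
#'
#' @param gene_ids Row identifiers.
#' @param design Tibble with columns `stage`, `n_case`, `n_control`; every
#'   arm needs >= 2 samples.
#' @param de_genes Genes carrying the planted condition effect.
#' @param effect_size Log2 shift applied to DE genes in cases (>= 0).
#' @param sigma Residual noise sd (> 0).
#' @param batch_shift Per-sample offset sd.
#' @param paired Generate matched case/control pairs (single-stage designs).
#' @param de_signs Optional named vector of +/-1 fixing each DE gene's
#'   direction (drawn at random when omitted); lets two studies share
#'   directions.
#' @param baseline_mean,baseline_sd Distribution of per-gene baselines
#'   (log2 scale).
#' @param name Study label.
#' @param rng_seed Integer seed.
#' @return An [expression_study()].
#' @export
simulate_expression <- function(gene_ids, design, de_genes = character(),
                                effect_size = 2, sigma = 0.5,
                                batch_shift = 0.2, paired = FALSE,
                                de_signs = NULL,
                                baseline_mean = 7, baseline_sd = 1.5,
                                name = "study", rng_seed = 42) {
  if (effect_size < 0) dg_stop("effect_size must be >= 0.")
  if (sigma <= 0) dg_stop("sigma must be > 0.")
  gene_ids <- norm_gene_id(gene_ids)
  de_genes <- norm_gene_id(de_genes)
  if (!all(de_genes %in% gene_ids)) {
    dg_stop("All de_genes must appear in gene_ids.")
  }
  design <- as_tibble(design)
  stopifnot(all(c("stage", "n_case", "n_control") %in% names(design)))
  if (any(design$n_case < 2) || any(design$n_control < 2)) {
    dg_stop("Every stage needs >= 2 samples per arm (variance not estimable).")
  }
  if (paired && any(design$n_case != design$n_control)) {
    dg_stop("A paired design needs equal case and control counts per stage.")
  }

  with_seed(rng_seed, {
    sheet <- purrr::map_dfr(seq_len(nrow(design)), function(i) {
      st <- design$stage[i]
      tibble(
        condition = c(rep("case", design$n_case[i]),
                      rep("control", design$n_control[i])),
        stage = st,
        pair = if (paired) {
          c(seq_len(design$n_case[i]), seq_len(design$n_control[i]))
        } else {
          NA_integer_
        }
      ) |>
        mutate(pair = if (paired) paste0(st, "_p", .data$pair) else NA)
    })
    sheet <- mutate(
      sheet,
      sample = sprintf("%s_s%03d", name, row_number()),
      .before = 1
    )
    if (!paired) sheet$pair <- NULL

    n_s <- nrow(sheet)
    baseline <- rnorm(length(gene_ids), baseline_mean, baseline_sd)
    if (is.null(de_signs)) {
      de_signs <- stats::setNames(
        sample(c(-1, 1), length(de_genes), replace = TRUE), de_genes
      )
    }
    effect <- stats::setNames(numeric(length(gene_ids)), gene_ids)
    effect[de_genes] <- de_signs[de_genes] * effect_size

    if (paired) {
      offs_by_pair <- stats::setNames(
        rnorm(length(unique(sheet$pair)), 0, batch_shift),
        unique(sheet$pair)
      )
      offsets <- offs_by_pair[sheet$pair]
    } else {
      offsets <- rnorm(n_s, 0, batch_shift)
    }

    is_case <- sheet$condition == "case"
    values <- matrix(
      rnorm(length(gene_ids) * n_s, 0, sigma),
      nrow = length(gene_ids), ncol = n_s,
      dimnames = list(gene_ids, sheet$sample)
    )
    values <- values + baseline +
      outer(effect, as.numeric(is_case)) +
      matrix(offsets, nrow = length(gene_ids), ncol = n_s, byrow = TRUE)

    expression_study(values, sheet, name = name)
  })
}

#' Generate module-biased pathway gene sets
#'
#' Each member is drawn from the planted module with probability
#' `module_bias`, else uniformly from the remaining genes, so pairwise set
#' overlaps are nonzero in expectation and consolidation is nontrivial.
#'
#' @param db An [interaction_db()].
#' @param module Planted module gene ids.
#' @param n_sets Number of sets (>= 2).
#' @param size_range Length-2 vector `(min, max)` of set sizes.
#' @param module_bias Per-member probability of drawing from the module.
#' @param include Genes force-included in two random sets each (used to
#'   plant entry-node ligands into pathway membership).
#' @param rng_seed Integer seed.
#' @return Gene-set tibble as from [read_gmt()].
#' @export
generate_pathways <- function(db, module, n_sets = 12, size_range = c(5, 10),
                              module_bias = 0.8, include = NULL,
                              rng_seed = 42) {
  if (n_sets < 2) dg_stop("n_sets must be >= 2.")
  if (size_range[1] > size_range[2]) {
    dg_stop("size_range min exceeds max.")
  }
  genes <- db_genes(db)
  if (size_range[2] > length(genes)) {
    dg_stop("Maximum set size exceeds the gene count.")
  }
  module <- intersect(norm_gene_id(module), genes)
  other <- setdiff(genes, module)

  with_seed(rng_seed, {
    sets <- purrr::map(seq_len(n_sets), function(i) {
      size <- sample(seq(size_range[1], size_range[2]), 1)
      n_mod <- min(stats::rbinom(1, size, module_bias), length(module))
      n_oth <- min(size - n_mod, length(other))
      sort(c(sample(module, n_mod), sample(other, n_oth)))
    })
    if (!is.null(include)) {
      for (g in norm_gene_id(include)) {
        for (j in sample.int(n_sets, min(2L, n_sets))) {
          sets[[j]] <- sort(unique(c(sets[[j]], g)))
        }
      }
    }
    tibble(
      name = sprintf("SET%02d", seq_len(n_sets)),
      description = "synthetic pathway",
      genes = sets
    )
  })
}

#' Generate node annotations
#'
#' Assigns each gene a cellular localization, a harmful/protective effect
#' label and a transcription-factor flag. Genes named in
#' `force_extracellular` are always extracellular (the planted entry-node
#' ligands).
#'
#' @param db An [interaction_db()].
#' @param extracellular_fraction Probability of the extracellular label for
#'   genes not forced; the rest split evenly over membrane / cytoplasm /
#'   nucleus.
#' @param harmful_fraction Probability of the harmful effect label; the
#'   remainder splits evenly between protective and unknown.
#' @param tf_fraction Probability of the transcription-factor flag.
#' @param force_extracellular Gene ids always labelled extracellular.
#' @param rng_seed Integer seed.
#' @return Annotation tibble (`id`, `localization`, `effect`, `tf`).
#' @export
generate_annotations <- function(db, extracellular_fraction = 0.05,
                                 harmful_fraction = 0.6, tf_fraction = 0.05,
                                 force_extracellular = NULL, rng_seed = 42) {
  stopifnot(extracellular_fraction >= 0, extracellular_fraction <= 1,
            harmful_fraction >= 0, harmful_fraction <= 1)
  genes <- db_genes(db)
  with_seed(rng_seed, {
    other_loc <- c("membrane", "cytoplasm", "nucleus")
    loc <- ifelse(
      runif(length(genes)) < extracellular_fraction,
      "extracellular",
      sample(other_loc, length(genes), replace = TRUE)
    )
    rest <- (1 - harmful_fraction) / 2
    eff <- sample(
      c("harmful", "protective", "unknown"), length(genes), replace = TRUE,
      prob = c(harmful_fraction, rest, rest)
    )
    ann <- tibble(
      id = genes,
      localization = loc,
      effect = eff,
      tf = runif(length(genes)) < tf_fraction
    )
    if (!is.null(force_extracellular)) {
      ann$localization[ann$id %in% norm_gene_id(force_extracellular)] <-
        "extracellular"
    }
    validate_annotations(ann)
  })
}

#' Generate a complete synthetic world
#'
#' One call wires every generator together: a scale-free interactome with a
#' planted, densified disease module; three extracellular "ligand" genes
#' wired into the module by directed regulation edges (the planted entry
#' nodes); two expression studies sharing one DE gene set with per-gene
#' directions held fixed across studies and stages — a paired single-stage
#' study and a three-stage case/control study; module-biased pathway sets
#' with the ligands planted into two sets each; annotations where the
#' ligands are the only extracellular genes; and known-miRNA labels for a
#' handful of module-targeting miRNAs.
#'
#' @param n_genes,n_mirnas,m_attach Interactome size parameters.
#' @param module_size,known_fraction,densification Planted-module
#'   parameters.
#' @param n_de Total planted DE genes (module members plus background
#'   genes).
#' @param effect_size,sigma,batch_shift Expression-simulation parameters.
#' @param n_per_arm Samples per arm in every contrast.
#' @param n_pathways,pathway_size_range,module_bias Pathway-set parameters.
#' @param n_known_mirnas miRNAs labelled as already disease-associated.
#' @param rng_seed Integer master seed; all component seeds derive from it.
#' @return A list of class `synthetic_world` (interactome, module labels,
#'   studies, pathways, annotations, miRNA labels, DE ground truth).
#' @export
generate_world <- function(n_genes = 500, n_mirnas = 60, m_attach = 3,
                           module_size = 20, known_fraction = 0.5,
                           densification = 0.3,
                           n_de = 200, effect_size = 2, sigma = 0.5,
                           batch_shift = 0.2, n_per_arm = 10,
                           n_pathways = 12, pathway_size_range = c(5, 10),
                           module_bias = 0.8, n_known_mirnas = 5,
                           rng_seed = 42) {
  seeds <- with_seed(rng_seed, sample.int(.Machine$integer.max, 10))

  db <- generate_interactome(n_genes, n_mirnas = n_mirnas,
                             m_attach = m_attach, rng_seed = seeds[1])
  planted <- plant_disease_module(db, module_size = module_size,
                                  known_fraction = known_fraction,
                                  densification = densification,
                                  rng_seed = seeds[2])
  db <- planted$db
  genes <- db_genes(db)

  # three extracellular ligands wired into the module by directed regulation
  lig <- with_seed(seeds[3], {
    ligands <- sort(sample(setdiff(genes, planted$module), 3))
    lig_edges <- purrr::map_dfr(ligands, function(l) {
      tibble(source = l,
             target = sample(planted$module, sample(2:4, 1)),
             type = "direct regulation",
             directed = TRUE)
    })
    list(ligands = ligands, edges = lig_edges)
  })
  db <- interaction_db(bind_rows(db$edges, lig$edges), nodes = db$nodes)

  de_genes <- with_seed(seeds[4], {
    extra <- sample(setdiff(genes, c(planted$module, lig$ligands)),
                    max(0, n_de - length(planted$module)))
    sort(c(planted$module, extra))
  })
  de_signs <- with_seed(seeds[5], {
    stats::setNames(sample(c(-1, 1), length(de_genes), replace = TRUE),
                    de_genes)
  })

  study_paired <- simulate_expression(
    genes,
    design = tibble(stage = "mid", n_case = n_per_arm,
                    n_control = n_per_arm),
    de_genes = de_genes, effect_size = effect_size, sigma = sigma,
    batch_shift = batch_shift, paired = TRUE, de_signs = de_signs,
    name = "cortex", rng_seed = seeds[6]
  )
  study_staged <- simulate_expression(
    genes,
    design = tibble(stage = c("incipient", "moderate", "severe"),
                    n_case = n_per_arm, n_control = n_per_arm),
    de_genes = de_genes, effect_size = effect_size, sigma = sigma,
    batch_shift = batch_shift, de_signs = de_signs,
    name = "hippocampus", rng_seed = seeds[7]
  )

  pathways <- generate_pathways(
    db, module = planted$module, n_sets = n_pathways,
    size_range = pathway_size_range, module_bias = module_bias,
    include = lig$ligands, rng_seed = seeds[8]
  )

  annotations <- generate_annotations(
    db, extracellular_fraction = 0, harmful_fraction = 0.6,
    tf_fraction = 0.05, force_extracellular = lig$ligands,
    rng_seed = seeds[9]
  )

  mirna_targets <- filter(db$edges, .data$type == "miRNA regulation")
  known_mirnas <- with_seed(seeds[10], {
    hits <- unique(mirna_targets$source[
      mirna_targets$target %in% planted$module
    ])
    pool <- if (length(hits) >= n_known_mirnas) hits else db_mirnas(db)
    sort(sample(pool, min(n_known_mirnas, length(pool))))
  })

  structure(list(
    interactome = db,
    known_genes = planted$known_genes,
    planted_candidates = planted$planted_candidates,
    module = planted$module,
    ligands = lig$ligands,
    de_genes = de_genes,
    de_signs = de_signs,
    studies = list(cortex = study_paired, hippocampus = study_staged),
    pathways = pathways,
    mirna_targets = mirna_targets,
    known_mirnas = known_mirnas,
    annotations = annotations,
    rng_seed = rng_seed
  ), class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    paste0("<synthetic_world seed=%d> %d genes, %d miRNAs; module %d ",
           "(%d known / %d candidates); %d DE genes; %d pathway sets\n"),
    x$rng_seed, length(db_genes(x$interactome)),
    length(db_mirnas(x$interactome)), length(x$module),
    length(x$known_genes), length(x$planted_candidates),
    length(x$de_genes), nrow(x$pathways)
  ))
  invisible(x)
}

#' Write a synthetic world's input files to a directory
#'
#' Emits every file the pipeline consumes: expression matrix and sample
#' sheet per study, the typed edge table, the GMT pathway collection, the
#' known-gene and known-miRNA lists, and the annotation table.
#'
#' @param world A [generate_world()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(world$studies)) {
    write_expression(
      world$studies[[nm]],
      file.path(dir, paste0(nm, "_matrix.tsv")),
      file.path(dir, paste0(nm, "_samples.tsv"))
    )
  }
  write_edges(world$interactome, file.path(dir, "edges.tsv"))
  write_gmt(world$pathways, file.path(dir, "pathways.gmt"))
  write_id_list(world$known_genes, file.path(dir, "known_genes.txt"))
  write_id_list(world$known_mirnas, file.path(dir, "known_mirnas.txt"))
  write_annotations(world$annotations, file.path(dir, "annotations.tsv"))
  invisible(dir)
}
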