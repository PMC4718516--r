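# End-to-end orchestration: one config drives simulate-or-load, moderated
# differential expression, seed selection, network construction, topology,
# guilt-by-association, enrichment, mechanism and miRNA stages, writing
# every stage's outputs plus a run manifest to one directory.

#' Default pipeline configuration
#'
#' Thresholds default to the analysis' canonical values: SDEG tier
#' `alpha = 0.05`, seed tier `alpha_final = 0.01`, SPNW seed degree cutoff
#' `min_db_degree = 25` with `max_len = 2`, enrichment `alpha` 0.05,
#' `top_k = 25` centrality lists and a degree hub threshold of 10. For
#' synthetic-world runs `min_db_degree` is set to 0: the synthetic
#' interactome is far smaller than a curated literature database and has no
#' comparable degree scale.
#'
#' @param synthetic `TRUE` for a synthetic-world run.
#' @return Named list of configuration values.
#' @export
default_config <- function(synthetic = TRUE) {
  list(
    inputs = NULL,          # named file paths; NULL = generate a world
    world = list(),         # overrides passed to generate_world()
    alpha = 0.05,
    alpha_final = 0.01,
    min_db_degree = if (synthetic) 0 else 25,
    max_len = 2,
    enrich_alpha = 0.05,
    top_k = 25,
    degree_hub_threshold = 10,
    min_known_neighbors = 1,
    n_key_candidates = 3,
    rng_seed = 42
  )
}

#' Read a pipeline configuration file
#'
#' YAML key-value file; missing keys fall back to [default_config()].
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_config(synthetic = is.null(cfg$inputs)), cfg)
}

load_pipeline_inputs <- function(cfg) {
  if (is.null(cfg$inputs)) {
    world <- do.call(generate_world,
                     utils::modifyList(list(rng_seed = cfg$rng_seed),
                                       cfg$world))
    list(
      studies = world$studies,
      get_db = function() world$interactome,
      known_genes = world$known_genes,
      pathways = world$pathways,
      annotations = world$annotations,
      known_mirnas = world$known_mirnas,
      world = world
    )
  } else {
    inp <- cfg$inputs
    studies <- list()
    for (nm in names(inp$studies)) {
      studies[[nm]] <- read_expression(inp$studies[[nm]]$matrix,
                                       inp$studies[[nm]]$sheet, name = nm)
    }
    # the edge table is read lazily, at the first stage that needs the
    # interactome, so earlier stages complete from expression data alone
    db_cache <- new.env(parent = emptyenv())
    list(
      studies = studies,
      get_db = function() {
        if (is.null(db_cache$db)) db_cache$db <- read_edges(inp$edges)
        db_cache$db
      },
      known_genes = read_id_list(inp$known_genes),
      pathways = read_gmt(inp$pathways),
      annotations = read_annotations(inp$annotations),
      known_mirnas = read_id_list(inp$known_mirnas, mirna = TRUE),
      world = NULL
    )
  }
}

#' Run the full analysis pipeline
#'
#' Executes simulate-or-load, differential expression, seed selection,
#' network construction (direct, SPNW, compact), topology,
#' guilt-by-association, gene-set enrichment, mechanism-network and miRNA
#' stages in order. Every stage writes its outputs to `outdir`; a run
#' manifest records the seed and every threshold used. A stage failure
#' halts the run with the stage name and the last successfully written
#' artifact. Identical configuration and inputs produce byte-identical
#' output files.
#'
#' @param config Configuration list (see [default_config()]) or path to a
#'   YAML file.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(config = default_config(), outdir) {
  cfg <- if (is.character(config)) read_config(config) else {
    utils::modifyList(default_config(synthetic = is.null(config$inputs)),
                      config)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  last_artifact <- "<none>"
  note <- function(path) last_artifact <<- path
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      dg_stop(sprintf(
        "Pipeline halted at stage '%s' (last good artifact: %s): %s",
        name, last_artifact, conditionMessage(e)
      ), class = "dgnet_pipeline_error")
    })
  }
  out <- function(...) file.path(outdir, ...)
  log_lines <- character(0)
  log_stage <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  inputs <- stage("inputs", {
    x <- load_pipeline_inputs(cfg)
    if (!is.null(x$world)) {
      write_world(x$world, out("inputs"))
      note(out("inputs"))
    }
    log_stage("inputs: %d studies loaded", length(x$studies))
    x
  })

  contrasts <- stage("dge", {
    cs <- lapply(inputs$studies, study_contrasts)
    for (st in names(cs)) {
      for (ct in names(cs[[st]])) {
        f <- out(sprintf("dge_%s_%s.tsv", st, ct))
        readr::write_tsv(tidy(cs[[st]][[ct]]), f, progress = FALSE)
        note(f)
      }
    }
    log_stage("dge: %d contrasts fit",
              sum(lengths(cs)))
    cs
  })

  seeds <- stage("seeds", {
    sdeg_sets <- list()
    for (st in names(contrasts)) {
      for (ct in names(contrasts[[st]])) {
        sdeg_sets[[paste(st, ct, sep = ".")]] <-
          select_sdegs(contrasts[[st]][[ct]], cfg$alpha)
      }
    }
    sds <- final_seeds(contrasts, cfg$alpha_final)
    write_id_list(sds$genes, out("seeds.txt"))
    note(out("seeds.txt"))
    venn <- NULL
    staged <- sdeg_sets[lengths(sdeg_sets) > 0]
    if (length(staged) >= 2) {
      venn <- venn_regions(head(staged, 4))
      readr::write_tsv(venn$regions, out("venn_regions.tsv"),
                       progress = FALSE)
      note(out("venn_regions.tsv"))
    }
    log_stage("seeds: %d SDEG lists -> union %d at alpha=%g -> %d seeds at alpha_final=%g",
              length(sdeg_sets), length(combine_studies(sdeg_sets)),
              cfg$alpha, length(sds$genes), cfg$alpha_final)
    list(seeds = sds, sdeg_sets = sdeg_sets, venn = venn)
  })

  networks <- stage("network", {
    db <- inputs$get_db()
    direct <- direct_interaction_network(seeds$seeds, db)
    spnw <- shortest_path_network(seeds$seeds, db,
                                  min_db_degree = cfg$min_db_degree,
                                  max_len = cfg$max_len)
    export_network(direct, out("network_direct.tsv"), "tsv")
    export_network(spnw, out("network_spnw.tsv"), "tsv")
    readr::write_tsv(spnw$nodes, out("network_spnw_nodes.tsv"),
                     progress = FALSE)
    note(out("network_spnw_nodes.tsv"))
    log_stage("network: direct %d nodes / %d edges; spnw %d nodes / %d edges",
              nrow(direct$nodes), nrow(direct$edges),
              nrow(spnw$nodes), nrow(spnw$edges))
    list(direct = direct, spnw = spnw, db = db)
  })

  topology <- stage("topology", {
    cent <- compute_centralities(networks$spnw)
    readr::write_tsv(cent, out("topology_spnw.tsv"), progress = FALSE)
    note(out("topology_spnw.tsv"))
    log_stage("topology: %d nodes scored; spnw average degree %.2f",
              nrow(cent), average_degree(networks$spnw))
    cent
  })

  gba <- stage("gba", {
    categories <- categorize_nodes(networks$spnw, seeds$seeds,
                                   inputs$known_genes)
    cand <- categories$node[categories$category %in%
                              c("interest_sdeg", "interest_connector")]
    scores <- gba_counts(networks$spnw, cand, inputs$known_genes)
    report <- prioritize(categories, scores, topology,
                         min_known_neighbors = cfg$min_known_neighbors,
                         topk_centrality = cfg$top_k)
    readr::write_tsv(report, out("gba_candidates.tsv"), progress = FALSE)
    note(out("gba_candidates.tsv"))

    keep <- union(
      categories$node[categories$known],
      report$node
    )
    compact <- compact_network(networks$spnw, keep)
    export_network(compact, out("network_compact.tsv"), "tsv")
    cent_compact <- compute_centralities(compact)
    readr::write_tsv(cent_compact, out("topology_compact.tsv"),
                     progress = FALSE)
    note(out("topology_compact.tsv"))
    log_stage("gba: %d candidates reported; compact %d nodes, avg degree %.2f, %d hubs (degree > %d)",
              nrow(report), nrow(compact$nodes), average_degree(compact),
              sum(cent_compact$degree > cfg$degree_hub_threshold),
              cfg$degree_hub_threshold)
    list(categories = categories, scores = scores, report = report,
         compact = compact, compact_centralities = cent_compact)
  })

  enrichment <- stage("enrich", {
    # the enrichment query is the compact network's gene set: the
    # concentrated disease core, not the full seed list
    background <- db_genes(networks$db)
    query <- intersect(gba$compact$nodes$id, background)
    tab <- enrich(query, inputs$pathways, background,
                  alpha = cfg$enrich_alpha)
    readr::write_tsv(tab, out("enrichment.tsv"), progress = FALSE)
    note(out("enrichment.tsv"))
    log_stage("enrich: %d sets tested, %d significant at p_adj < %g",
              nrow(tab), sum(tab$significant), cfg$enrich_alpha)
    tab
  })

  mechanism <- stage("mechanism", {
    sel_names <- enrichment$name[enrichment$significant]
    selected <- filter(inputs$pathways, .data$name %in% sel_names)
    if (nrow(selected) == 0) {
      dg_stop("No significantly enriched pathway to consolidate.")
    }
    genes <- consolidate_pathway_genes(selected)
    write_id_list(genes, out("mechanism_genes.txt"))
    mech <- build_mechanism_network(genes, networks$db)
    export_network(mech, out("network_mechanism.tsv"), "tsv")
    entry <- detect_entry_nodes(mech, inputs$annotations)
    readr::write_tsv(entry, out("mechanism_entry_nodes.tsv"),
                     progress = FALSE)
    effects <- label_effects(mech, inputs$annotations)
    readr::write_tsv(effects$summary, out("mechanism_effects.tsv"),
                     progress = FALSE)
    note(out("mechanism_effects.tsv"))
    log_stage("mechanism: %d pathways -> %d consolidated genes; %d entry nodes",
              nrow(selected), length(genes), nrow(entry))
    list(selected = selected, genes = genes, network = mech,
         entry_nodes = entry, effects = effects)
  })

  mirna <- stage("mirna", {
    key_genes <- union(mechanism$entry_nodes$node,
                       head(gba$report$node, cfg$n_key_candidates))
    rep <- mirnas_targeting(key_genes, networks$db)
    cls <- classify_mirnas(rep$mirna_set, inputs$known_mirnas)
    readr::write_tsv(rep$mirna_counts, out("mirna_key_gene_report.tsv"),
                     progress = FALSE)
    regnet <- mirna_regulatory_network(seeds$seeds, networks$db,
                                       inputs$annotations)
    hubs <- if (any(regnet$nodes$role == "miRNA")) {
      hub_mirna(regnet)
    } else {
      tibble()
    }
    if (nrow(hubs) > 0) {
      readr::write_tsv(hubs, out("mirna_hubs.tsv"), progress = FALSE)
      note(out("mirna_hubs.tsv"))
    }
    log_stage("mirna: %d miRNAs target the %d key genes (%d known, %d novel); regulatory net %d nodes",
              length(rep$mirna_set), length(key_genes),
              length(cls$known), length(cls$novel), nrow(regnet$nodes))
    list(key_genes = key_genes, report = rep, classes = cls,
         regulatory = regnet, hubs = hubs)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("dgnet")),
    rng_seed = cfg$rng_seed,
    thresholds = cfg[c("alpha", "alpha_final", "min_db_degree", "max_len",
                       "enrich_alpha", "top_k", "degree_hub_threshold",
                       "min_known_neighbors")],
    synthetic = is.null(cfg$inputs),
    input_hashes = if (!is.null(cfg$inputs)) {
      as.list(tools::md5sum(unlist(cfg$inputs, use.names = FALSE)))
    },
    stages = log_lines
  )
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))

  invisible(list(
    config = cfg, inputs = inputs, contrasts = contrasts, seeds = seeds,
    networks = networks, topology = topology, gba = gba,
    enrichment = enrichment, mechanism = mechanism, mirna = mirna,
    manifest = manifest
  ))
}

#' Create a reproducible demo workspace
#'
#' Generates a synthetic world sized like a two-study brain expression
#' analysis, writes every pipeline input file to `outdir`, and copies the
#' curated pathway and miRNA fixtures alongside them.
#'
#' @param outdir Target directory.
#' @param rng_seed Integer seed.
#' @return Invisibly, the world object.
#' @export
make_demo <- function(outdir, rng_seed = 42) {
  world <- generate_world(rng_seed = rng_seed)
  write_world(world, outdir)
  file.copy(dg_extdata("ad_kegg_pathways.gmt"),
            file.path(outdir, "ad_kegg_pathways.gmt"), overwrite = TRUE)
  file.copy(dg_extdata("ad_known_mirnas.txt"),
            file.path(outdir, "ad_known_mirnas.txt"), overwrite = TRUE)
  file.copy(dg_extdata("ad_novel_mirnas.txt"),
            file.path(outdir, "ad_novel_mirnas.txt"), overwrite = TRUE)
  invisible(world)
}
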