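# Synthetic-data generators: construction rules, statistical calibration,
# planted ground truth, determinism.

test_that("preferential attachment with m = 1 grows a tree", {
  db <- generate_interactome(50, m_attach = 1, rng_seed = 1)
  expect_equal(nrow(db$edges), 49)
  g <- dgnet:::db_igraph(db)
  expect_true(igraph::is_connected(g))
})

test_that("the degree distribution is heavier-tailed than Erdos-Renyi", {
  db <- generate_interactome(200, m_attach = 3, rng_seed = 11)
  g <- dgnet:::db_igraph(db)
  deg_pa <- sort(igraph::degree(g), decreasing = TRUE)
  m <- igraph::ecount(g)
  # ER graph with the same node and edge count, same seed budget
  set.seed(11)
  g_er <- igraph::sample_gnm(200, m)
  deg_er <- sort(igraph::degree(g_er), decreasing = TRUE)
  top_share <- function(d) sum(d[seq_len(20)]) / sum(d)
  expect_gt(top_share(deg_pa), top_share(deg_er))
})

test_that("miRNA wiring obeys the construction rules", {
  db <- generate_interactome(200, n_mirnas = 20, rng_seed = 3)
  mirs <- db_mirnas(db)
  expect_length(mirs, 20)
  mir_edges <- db$edges[db$edges$type == "miRNA regulation", ]
  out_deg <- table(factor(mir_edges$source, levels = mirs))
  expect_true(all(out_deg >= 1 & out_deg <= 10))
  # miRNAs receive nothing and touch no protein-type edge
  expect_false(any(db$edges$target %in% mirs))
  prot <- db$edges[db$edges$type != "miRNA regulation", ]
  expect_false(any(prot$source %in% mirs))
})

test_that("interactome configuration errors are caught", {
  w <- dgnet:::default_edge_type_weights()
  w["miRNA regulation"] <- 0
  expect_error(generate_interactome(50, n_mirnas = 5, edge_type_weights = w),
               "miRNA regulation")
  expect_error(generate_interactome(50, edge_type_weights = -w))
  expect_error(generate_interactome(2, m_attach = 5))
})

test_that("planted modules split correctly and densify", {
  db <- generate_interactome(100, rng_seed = 5)
  pm <- plant_disease_module(db, module_size = 10, known_fraction = 0.5,
                             rng_seed = 5)
  expect_length(pm$known_genes, 5)
  expect_length(pm$planted_candidates, 5)
  expect_length(intersect(pm$known_genes, pm$planted_candidates), 0)
  expect_true(all(pm$module %in% db_genes(pm$db)))

  # densification 1 induces a clique on the module
  pm2 <- plant_disease_module(db, module_size = 6, densification = 1,
                              rng_seed = 6)
  g <- dgnet:::db_igraph(pm2$db, nodes = db_genes(pm2$db))
  sub <- igraph::induced_subgraph(g, pm2$module)
  expect_equal(igraph::ecount(sub), choose(6, 2))

  expect_error(plant_disease_module(db, module_size = 1), "module_size")
})

test_that("densification raises candidate within-module degree", {
  db <- generate_interactome(500, rng_seed = 9)
  before <- igraph::degree(dgnet:::db_igraph(db))
  pm <- plant_disease_module(db, module_size = 20, densification = 0.3,
                             rng_seed = 9)
  after <- igraph::degree(dgnet:::db_igraph(pm$db))
  expect_gt(mean(after[pm$planted_candidates]),
            mean(before[pm$planted_candidates]))
})

test_that("null expression simulation is calibrated at alpha = 0.05", {
  genes <- sprintf("G%04d", 1:500)
  st <- simulate_expression(
    genes, tibble::tibble(stage = "mid", n_case = 10, n_control = 10),
    de_genes = character(), effect_size = 0, sigma = 1, batch_shift = 0,
    rng_seed = 20
  )
  stats <- ebayes_moderate(fit_contrast(st))
  frac <- mean(tidy(stats)$p < 0.05)
  # binomial: 0.05 +/- 2*sqrt(0.05*0.95/500)
  expect_lt(abs(frac - 0.05), 2 * sqrt(0.05 * 0.95 / 500))
})

test_that("strong effects are detected with near-certain power", {
  genes <- sprintf("G%04d", 1:300)
  de <- genes[1:30]
  st <- simulate_expression(
    genes, tibble::tibble(stage = "mid", n_case = 10, n_control = 10),
    de_genes = de, effect_size = 2, sigma = 0.5, rng_seed = 21
  )
  stats <- tidy(ebayes_moderate(fit_contrast(st)))
  expect_true(all(stats$p[stats$gene %in% de] < 0.01))
})

test_that("expression design preconditions hold", {
  genes <- c("G1", "G2")
  expect_error(simulate_expression(
    genes, tibble::tibble(stage = "s", n_case = 1, n_control = 5)
  ), "2 samples per arm")
  expect_error(simulate_expression(genes, tibble::tibble(
    stage = "s", n_case = 3, n_control = 3
  ), de_genes = "G9"), "de_genes")
})

test_that("pathway sets are module-biased and overlap", {
  db <- generate_interactome(500, rng_seed = 13)
  pm <- plant_disease_module(db, 20, rng_seed = 13)
  ps <- generate_pathways(pm$db, pm$module, n_sets = 12,
                          size_range = c(5, 10), module_bias = 0.8,
                          rng_seed = 13)
  expect_equal(nrow(ps), 12)
  union_size <- length(unique(unlist(ps$genes)))
  expect_lt(union_size, sum(lengths(ps$genes)))  # overlaps exist

  # full bias with max size below module size keeps every set inside it
  ps2 <- generate_pathways(pm$db, pm$module, n_sets = 5,
                           size_range = c(3, 5), module_bias = 1,
                           rng_seed = 14)
  expect_true(all(unlist(ps2$genes) %in% pm$module))

  expect_error(generate_pathways(pm$db, pm$module, size_range = c(9, 5)),
               "size_range")
})

test_that("annotation fractions behave binomially and respect forcing", {
  db <- generate_interactome(400, rng_seed = 15)
  ann <- generate_annotations(db, extracellular_fraction = 0,
                              harmful_fraction = 0.8, rng_seed = 15)
  n_h <- sum(ann$effect == "harmful")
  ci <- stats::qbinom(c(0.005, 0.995), 400, 0.8)
  expect_true(n_h >= ci[1] && n_h <= ci[2])
  expect_false(any(ann$localization == "extracellular"))

  ann2 <- generate_annotations(db, extracellular_fraction = 1,
                               harmful_fraction = 1, rng_seed = 15)
  expect_true(all(ann2$localization == "extracellular"))
  expect_true(all(ann2$effect == "harmful"))

  ann3 <- generate_annotations(db, extracellular_fraction = 0,
                               force_extracellular = "G0005",
                               rng_seed = 15)
  expect_equal(ann3$localization[ann3$id == "G0005"], "extracellular")
})

test_that("identical seeds reproduce the world bit-identically", {
  w1 <- generate_world(n_genes = 120, n_mirnas = 10, n_de = 30,
                       rng_seed = 77)
  w2 <- generate_world(n_genes = 120, n_mirnas = 10, n_de = 30,
                       rng_seed = 77)
  expect_identical(serialize(w1, NULL), serialize(w2, NULL))
  w3 <- generate_world(n_genes = 120, n_mirnas = 10, n_de = 30,
                       rng_seed = 78)
  expect_false(identical(serialize(w1, NULL), serialize(w3, NULL)))
})

test_that("world invariants hold", {
  w <- generate_world(n_genes = 200, n_mirnas = 20, n_de = 40,
                      rng_seed = 31)
  expect_length(intersect(w$known_genes, w$planted_candidates), 0)
  expect_true(all(c(w$known_genes, w$planted_candidates) %in%
                    w$interactome$nodes$id))
  for (st in w$studies) {
    expect_true(all(w$de_genes %in% rownames(st$values)))
  }
  expect_true(all(w$mirna_targets$type == "miRNA regulation"))
  # the three ligands are the only extracellular genes
  expect_setequal(
    w$annotations$id[w$annotations$localization == "extracellular"],
    w$ligands
  )
})

test_that("planted candidates out-neighbor random gene sets in known genes", {
  w <- generate_world(n_genes = 300, n_mirnas = 20, n_de = 50,
                      rng_seed = 41)
  g <- dgnet:::db_igraph(w$interactome)
  nb <- igraph::as_adj_list(g)
  ids <- igraph::V(g)$name
  names(nb) <- ids
  known_count <- function(set) {
    sum(vapply(set, function(v) {
      length(intersect(ids[as.integer(nb[[v]])], w$known_genes))
    }, numeric(1)))
  }
  obs <- known_count(w$planted_candidates)
  genes <- setdiff(db_genes(w$interactome), w$module)
  set.seed(41)
  null <- replicate(100, known_count(sample(genes,
                                            length(w$planted_candidates))))
  expect_gt(obs, mean(null))
  expect_gt(mean(obs > null), 0.95)
})
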