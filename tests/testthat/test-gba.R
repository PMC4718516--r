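# Node categorization and guilt-by-association ranking.

gba_fixture <- function() {
  # star: CAND at the center of 4 known leaves plus one unknown leaf
  dg_network(
    tibble::tibble(id = c("CAND", paste0("K", 1:4), "U1", "M9"),
                   role = c("connector", rep("seed", 4), "seed", "miRNA")),
    tibble::tibble(source = "CAND",
                   target = c(paste0("K", 1:4), "U1", "M9"),
                   type = "binding", directed = FALSE)
  )
}

test_that("categorization crosses role with known membership, excluding miRNAs", {
  net <- gba_fixture()
  cats <- categorize_nodes(net, seeds = c(paste0("K", 1:4), "U1"),
                           known = c("K1", "K2", "K3", "K4", "CAND2"))
  expect_false("M9" %in% cats$node)
  expect_equal(cats$category[cats$node == "K1"], "known_sdeg")
  expect_equal(cats$category[cats$node == "U1"], "interest_sdeg")
  expect_equal(cats$category[cats$node == "CAND"], "interest_connector")
  # exhaustive partition of gene nodes
  expect_equal(nrow(cats), sum(net$nodes$role != "miRNA"))
  expect_false(any(duplicated(cats$node)))
  expect_error(categorize_nodes(net, "K1", character()), "empty")
})

test_that("known-neighbor counts match direct adjacency intersection", {
  net <- gba_fixture()
  known <- paste0("K", 1:4)
  sc <- gba_counts(net, c("CAND", "U1"), known)
  expect_equal(sc$known_neighbor_count[sc$node == "CAND"], 4)
  expect_equal(sc$known_neighbors[sc$node == "CAND"], "K1,K2,K3,K4")
  expect_equal(sc$known_neighbor_count[sc$node == "U1"], 0)
  expect_equal(sc$node, c("CAND", "U1"))  # sorted by count desc
  # U1 touches CAND which touches known: second-level flag set
  expect_true(sc$known_within_2[sc$node == "U1"])
  expect_error(gba_counts(net, "GHOST", known), "outside")
})

test_that("counts equal a brute-force oracle on random networks", {
  for (seed in c(21, 22)) {
    net <- random_net(40, 0.12, seed = seed)
    set.seed(seed)
    known <- sample(net$nodes$id, 8)
    cand <- setdiff(net$nodes$id, known)[1:10]
    sc <- gba_counts(net, cand, known)
    A <- oracle_adjacency(net)
    for (cd in cand) {
      nb <- colnames(A)[A[cd, ] == 1]
      expect_equal(sc$known_neighbor_count[sc$node == cd],
                   length(intersect(nb, known)))
    }
  }
})

test_that("adding a known gene never lowers a count, relabeling edges changes nothing", {
  net <- random_net(30, 0.15, seed = 23)
  set.seed(23)
  known <- sample(net$nodes$id, 5)
  cand <- setdiff(net$nodes$id, known)
  sc1 <- gba_counts(net, cand, known)
  sc2 <- gba_counts(net, cand, c(known, sample(cand, 1)))
  both <- dplyr::inner_join(sc1, sc2, by = "node")
  expect_true(all(both$known_neighbor_count.y >=
                    both$known_neighbor_count.x))

  net_relab <- net
  net_relab$edges$type <- "expression"
  expect_equal(gba_counts(net_relab, cand, known), sc1)
})

test_that("permutation p-values respect their bounds and detect planted structure", {
  # a candidate whose neighbors are all known, inside a larger graph so
  # the permutation pool contains plenty of non-neighbors
  extra <- sprintf("X%02d", 1:12)
  net <- dg_network(
    tibble::tibble(id = c("CAND", paste0("K", 1:4), "U1", extra),
                   role = "gene"),
    dplyr::bind_rows(
      tibble::tibble(source = "CAND", target = c(paste0("K", 1:4), "U1"),
                     type = "binding", directed = FALSE),
      tibble::tibble(source = extra[-1], target = extra[-12],
                     type = "binding", directed = FALSE)
    )
  )
  known <- paste0("K", 1:4)
  # zero known neighbors: p = 1
  expect_equal(gba_permutation_test(net, "X05", known, n_perm = 200), 1)
  # all neighbors known: small but bounded below
  p <- gba_permutation_test(net, "CAND", known, n_perm = 200,
                            rng_seed = 1)
  expect_gte(p, 1 / 201)
  expect_lt(p, 0.1)
  expect_error(gba_permutation_test(net, "CAND", known, n_perm = 10),
               "n_perm")
})

test_that("planted candidates get lower permutation p than degree-matched genes", {
  w <- generate_world(n_genes = 250, n_mirnas = 10, n_de = 40,
                      rng_seed = 24)
  net <- shortest_path_network(w$de_genes, w$interactome,
                               min_db_degree = 0, max_len = 2)
  in_net <- intersect(w$planted_candidates, net$nodes$id)
  p_cand <- vapply(in_net, function(cd) {
    gba_permutation_test(net, cd, w$known_genes, n_perm = 200,
                         rng_seed = 7)
  }, numeric(1))
  g <- igraph::graph_from_data_frame(
    net$edges[, c("source", "target")], directed = FALSE,
    vertices = data.frame(name = net$nodes$id)
  )
  deg <- igraph::degree(igraph::simplify(g))
  pool <- setdiff(net$nodes$id, c(w$module, w$known_genes))
  set.seed(24)
  matched <- vapply(in_net, function(cd) {
    cands <- pool[abs(deg[pool] - deg[cd]) <= 2]
    if (length(cands) == 0) cands <- pool
    sample(cands, 1)
  }, "")
  p_null <- vapply(matched, function(cd) {
    gba_permutation_test(net, cd, w$known_genes, n_perm = 200,
                         rng_seed = 7)
  }, numeric(1))
  expect_lt(median(p_cand), median(p_null))
})

test_that("the prioritization report sorts by evidence and flags top lists", {
  net <- gba_fixture()
  seeds <- c(paste0("K", 1:4), "U1")
  known <- paste0("K", 1:4)
  cats <- categorize_nodes(net, seeds, known)
  sc <- gba_counts(net, cats$node[cats$category %in%
                                    c("interest_sdeg",
                                      "interest_connector")], known)
  cent <- compute_centralities(net)
  rep1 <- prioritize(cats, sc, cent, min_known_neighbors = 1,
                     topk_centrality = 3)
  expect_equal(rep1$node, "CAND")
  expect_true(all(rep1$known_neighbor_count >= 1))
  expect_true(rep1$top_degree[1] && rep1$top_betweenness[1])

  rep0 <- prioritize(cats, sc, cent, min_known_neighbors = 0)
  expect_true("U1" %in% rep0$node)
  expect_equal(rep0$node[1], "CAND")  # highest count first
})

test_that("randomizing the known list destroys planted-candidate recovery", {
  w <- generate_world(n_genes = 250, n_mirnas = 10, n_de = 40,
                      rng_seed = 26)
  net <- shortest_path_network(w$de_genes, w$interactome,
                               min_db_degree = 0, max_len = 2)
  cats <- categorize_nodes(net, w$de_genes, w$known_genes)
  interest <- cats$node[cats$category %in% c("interest_sdeg",
                                             "interest_connector")]
  top20 <- function(known) {
    sc <- gba_counts(net, setdiff(interest, known), known)
    cent <- compute_centralities(net)
    head(prioritize(cats, sc, cent)$node, 20)
  }
  real_hits <- mean(w$planted_candidates %in% top20(w$known_genes))
  set.seed(26)
  gene_pool <- setdiff(net$nodes$id, w$planted_candidates)
  null_hits <- mean(w$planted_candidates %in%
                      top20(sample(gene_pool, length(w$known_genes))))
  expect_gt(real_hits, null_hits)
  expect_gte(real_hits, 0.6)
})
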