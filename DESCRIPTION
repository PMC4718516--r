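Package: dgnet
Title: Network-Topology Prioritization of Disease Genes from Case/Control
    Expression Studies and a Typed Interactome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Turns case/control brain expression studies and a typed
    molecular-interaction database into prioritized disease-gene candidates,
    an integrated mechanism network and candidate regulatory microRNAs.
    Implements moderated t-statistics with empirical-Bayes variance
    shrinkage, two-tier seed-gene selection, direct-interaction and
    shortest-path network construction with degree filtering, Brandes
    betweenness and component-scaled closeness centralities,
    guilt-by-association ranking against known disease genes, local
    hypergeometric gene-set over-representation with Benjamini-Hochberg
    correction, mechanism-network consolidation with extracellular
    entry-node detection, and a miRNA-target regulatory overlay. A
    synthetic-data generator produces scale-free typed interactomes with
    planted disease modules and multi-stage expression studies so the full
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
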