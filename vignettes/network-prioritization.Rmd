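---
title: "Network-topology prioritization of disease genes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-topology prioritization of disease genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgnet)
```

`dgnet` prioritizes disease-gene candidates by combining case/control
expression evidence with the topology of a typed molecular-interaction
network, then layers pathway enrichment, an integrated mechanism network
and miRNA regulation on top. This vignette documents the statistical
models, the tunable parameters, the synthetic-data generator that the
package is validated against, and the design choices made where the design
was genuinely open.

## The moderated t model

For gene $g$ in one case/control contrast we compute the log2 fold change
$\hat\beta_g$ (case minus control), the residual variance $s^2_g$ on $d_g$
degrees of freedom, and the unscaled variance multiplier $v_g$
($1/n_1 + 1/n_2$ for independent arms; $1/n$ pairs for paired designs,
with $d_g = n - 1$). Variances are moderated with a conjugate
inverse-chi-square ensemble prior: given prior degrees of freedom $d_0$
and prior variance $s_0^2$,

$$\tilde s^2_g = \frac{d_0 s_0^2 + d_g s^2_g}{d_0 + d_g},\qquad
  \tilde t_g = \frac{\hat\beta_g}{\tilde s_g \sqrt{v_g}},$$

with two-sided p-values from a t distribution on $d_0 + d_g$ degrees of
freedom (capped at $10^6$ when the prior is infinite).

The prior is estimated by moment matching on $z_g = \log s^2_g$. Under the
model, $z_g$ equals $\log s_0^2$ plus independent contributions whose mean
and variance are digamma/trigamma functions of $d_g/2$ and $d_0/2$, so the
empirical mean and variance of $z_g$ identify $(d_0, s_0^2)$. The trigamma
inversion is done by monotone bisection on a bracket of $[10^{-8}, 10^8]$
(the function is strictly decreasing, so bisection is exact to machine
tolerance). When the observed spread of $z_g$ does not exceed the
within-gene chi-square contribution, the estimator returns $d_0 = \infty$
and every posterior variance equals $s_0^2$; genes are then ranked by
$|\hat\beta_g|$. Genes with $s^2_g = 0$ are excluded from prior estimation
but still receive a well-defined posterior variance. The tests verify the
estimator recovers a planted $(d_0 = 4, s_0^2 = 1)$ within $[2.5, 6]$
across seeds and agrees with the reference empirical-Bayes implementation
in the `limma` package to four decimals.

Normalization is quantile normalization (every column mapped onto the mean
order-statistic profile; ties receive the mean of their quantile targets)
plus, for probe-level input, Tukey median-polish summarization per gene.
Probe-level convolution background correction is out of scope: inputs
begin at a numeric matrix. Where several probes map to one gene after
summarization, the probe with the smallest moderated p per contrast is
kept.

## Seed selection

Two thresholds drive the funnel, both strict inequalities:

* `alpha = 0.05` — a gene with $p < 0.05$ in a contrast is an SDEG;
* `alpha_final = 0.01` — a gene with $p < 0.01$ in *any* contrast of
  *any* study becomes a seed gene.

A gene qualifies through any contrast because the analysis pools evidence
across stages and studies before the stricter cut; per-gene provenance
records which contrasts it passed. No multiple-testing correction is
applied at this stage by design — the stricter 0.01 tier plays that role —
though BH-adjusted enrichment p-values are used downstream. For
multi-set overlaps the package reports both readings of a Venn "overlap":
the full k-way intersection and the union of all multi-set regions, since
the two can differ by an order of magnitude.

## Networks

* **Direct-interaction network**: the interactome subgraph induced on
  seeds; isolated seeds are dropped by default.
* **SPNW**: seeds whose degree in the *full database* reaches
  `min_db_degree` (default 25) are expanded with every node on *any*
  shortest path of length ≤ `max_len` (default 2) between a qualifying
  pair. Taking all shortest paths, not one arbitrary path per pair, makes
  the result independent of traversal order. Distances use the undirected
  simple view; a directed mode was considered and rejected as the default
  because the downstream centrality descriptors are undirected.
* **Compact SPNW**: starting from the nodes worth keeping (known genes
  plus reported candidates), connectors are added greedily — each addition
  joins the largest number of currently-separate components, ties broken
  by higher SPNW degree then lexicographic id — until one component
  remains or the budget is exhausted. An exact Steiner tree would be
  overkill here: the step it replaces was manual curation of "a few
  additional connecting genes", and the greedy heuristic is deterministic
  and locally optimal at every step (verified exhaustively in the tests).

Centralities are computed on the undirected simple view: degree; Brandes
betweenness normalized by $2/((n-1)(n-2))$; and closeness with the
Wasserman–Faust component correction, $\frac{n_C-1}{\sum d} \cdot
\frac{n_C-1}{n-1}$ within a component of size $n_C$, so small disconnected
components cannot dominate the ranking. Ranks are 1-based dense ranks;
top-k lists break ties lexicographically so output is order-invariant.

## Guilt by association

A candidate's primary score is its count of first-level neighbors on the
known-disease-gene list. Second-level evidence (a known gene within
distance 2) is reported as a separate flag, never mixed into the count.
The optional permutation p-value permutes the known-label assignment over
non-candidate gene nodes, keeping the topology fixed:
$p = (1 + \#\{\text{permuted} \ge \text{observed}\})/(n_{perm}+1)$. The
final report sorts by (known-neighbor count, betweenness rank) and flags
membership in each top-25 centrality list.

## Enrichment and mechanism

Over-representation uses the hypergeometric upper tail (evaluated through
the distribution's log-space tail) with BH correction across sets; sets
smaller than 3 after background intersection are skipped. The background
defaults to the interactome's gene universe — fold-enrichment values are
only comparable for a fixed background, so fold values computed against
other universes are not reproduction targets. The plain hypergeometric is
used rather than any modified variant. The enrichment query in the
pipeline is the compact network's gene set: the concentrated disease core,
which is where pathway signal lives, rather than the diluted full seed
list.

"Common genes" of the selected pathways means the deduplicated **union**
of their member lists, not the intersection — with the bundled curated
collection the twelve lists share no single gene, while their union is
exactly the 37-gene mechanism list, which forces this reading. The
mechanism network is the typed induced subgraph on those genes, keeping
direction and isolated members (the gene list is fixed by consolidation,
not by connectivity). Entry nodes are extracellular-annotated genes with
at least one edge into the non-extracellular core; effect labels
(harmful/protective/unknown) are curated inputs, not inferred — the
original assignments came from literature search, which is out of scope.

## miRNA overlay

miRNA identifiers are normalized by lowercasing and removing a hyphen that
separates a letter from a trailing copy digit ("miR-29b-1" and "miR-29b1"
become one id), while a hyphen between digits is kept ("miR-101-1" must
not merge with "miR-1011"). The regulatory network over seeds is the union
of two edge filters: miRNA-regulation edges into seeds, and promoter
binding/expression edges from TF-flagged seeds into seeds. Hub miRNAs are
ranked lexicographically by (degree, closeness, betweenness).

The bundled miRNA-to-key-gene edge table is **synthetic**: the per-gene
regulator counts follow the published bookkeeping, but the individual
pairings stand in for proprietary curated content and are labelled as such.

## The synthetic world

`generate_world()` produces every pipeline input with planted ground
truth. Defaults, chosen once as the validation conditions:

| parameter | default | what it emulates |
|---|---|---|
| `n_genes`, `n_mirnas` | 500, 60 | desk-scale interactome universe |
| `m_attach` | 3 | preferential-attachment density; hubby degree skew of curated interactomes |
| `module_size`, `densification` | 20, 0.3 | a coherent disease module, denser than background |
| `known_fraction` | 0.5 | half the module already "known", half withheld as candidates |
| `n_de` | 200 | planted DE genes (module plus background); yields roughly 210 seeds at the 0.01 tier |
| `effect_size`, `sigma` | 2, 0.5 | strong, clearly detectable dysregulation (log2 units) |
| `batch_shift` | 0.2 | per-sample technical offsets; shared within pairs in the paired study |
| `n_per_arm` | 10 | per-arm sample size of every contrast |
| pathways | 12 sets, size 5–10, bias 0.8 | overlapping, module-biased collections |

Two studies are generated: a paired single-stage study (matched
case/control pairs sharing a sample offset) and a three-stage study
(incipient/moderate/severe, each with its own control arm). One DE gene
set with per-gene signs drawn once is shared by both, emulating consistent
dysregulation across stages and tissues. Three ligand genes outside the
module are wired into it by directed regulation edges, force-included in
two pathway sets each, and are the only extracellular-annotated genes —
the planted truth for entry-node detection. For synthetic runs the SPNW
degree filter defaults to 0: a 500-node generated interactome has no
degree scale comparable to a curated literature database, where the
default cutoff of 25 applies.

What the generator does **not** emulate: probe-level artifacts and spatial
effects, realistic miRNA seed-sequence matching, correlated co-expression
beyond the shared sample offsets, and annotation noise. Passing the
planted-recovery tests therefore shows the pipeline's logic is correct
under its own assumptions, not that those assumptions hold for any given
real dataset.

## Numerical choices and degenerate inputs

* Strict inequalities at every p-value threshold.
* All randomness flows through explicit integer seeds; component seeds
  are derived from one master seed, and the package never disturbs the
  caller's RNG state. Identical seed ⇒ bit-identical world and
  byte-identical pipeline output files.
* Quantile normalization of a single column is the identity, with a
  warning. A contrast arm left empty by a stage filter is an error naming
  the filter; fewer than 2 samples per arm is an error (variance not
  estimable).
* Empty seed sets produce a warning and a graceful halt of downstream
  stages; networks with fewer than 3 nodes report unnormalized betweenness
  with a warning; isolated nodes have closeness 0.
* Ties: quantile targets are averaged; top-k lists and greedy connector
  choices break ties lexicographically (after the degree criterion); dense
  ranks share tied ranks.
* Validation sizes were chosen to keep the full suite around three
  minutes: oracle sweeps use graphs of ≤ 30–60 nodes, calibration uses
  500–2000 genes, and end-to-end recovery uses ten full 500-gene worlds.

## Known limitations

* The degree-≥-25 SPNW filter is meaningful only against a database with
  literature-interactome degree scale; against small custom databases it
  should be lowered (the synthetic default is 0).
* The enrichment background is the analysis universe, not an
  annotation-platform background, so fold-enrichment values are not
  comparable across tools with proprietary backgrounds.
* Effect labels and known-gene/miRNA lists are curated inputs; the
  package performs no literature mining.
* Paired and two-group designs only; multi-factor models,
  duplicate-correlation and array weights are out of scope.
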