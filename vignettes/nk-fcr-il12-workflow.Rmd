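---
title: "Methods: blocked-ANOVA differential expression and network centrality prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blocked-ANOVA differential expression and network centrality prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nkfcnet)
```

# The analysis problem

NK cells stimulated through the Fc receptor (immobilized IgG), through the
IL-12 receptor, or through both, mount transcriptional programs that are
partly shared and partly combination-specific. The design is a randomized
complete block: each of *b* donors (blocks) contributes expression
profiles under all *k* = 4 conditions (`medium`, `IgG`, `IL12`,
`IgG_IL12`), with duplicate arrays per donor × condition. The package
implements the full prioritization chain on such data: per-gene blocked
ANOVA with a triple significance filter, Venn partitioning of the
vs-medium call sets, hypergeometric category enrichment with seed
augmentation, and centrality ranking on a directed functional-linkage
network.

# The statistical model and its assumptions

For each gene the additive block–treatment model is fit on log2
intensities:

$$y_{dj} = \mu + \beta_d + \tau_j + \varepsilon_{dj}$$

with donors $d$ as blocks and conditions $j$ as treatments, **no
block × treatment interaction**, and
$\mathrm{df}_{error} = (b-1)(k-1)$. On a complete balanced design the
least-squares solution is the closed-form decomposition over cell, block
and grand means, which `fit_block_anova()` computes vectorized over all
genes; the test suite checks it against an explicit design-matrix `lm()`
oracle to 1e-10.

Pairwise *cell-mean comparison contrasts* use the pooled error variance:
$\hat\delta = \bar y_{\cdot j} - \bar y_{\cdot j'}$,
$SE = \sqrt{2\,MSE/b}$, two-sided p from Student's t. Six contrasts at
family level 0.05 give the Bonferroni per-contrast cutoff 0.05/6; the
pipeline's default is the 3-decimal rounding **0.008** for
reproducibility of published gene lists (`bonferroni_threshold()` returns
the exact value).

## The triple filter

A gene is called for a contrast only when all three hold (strict
inequalities):

| filter | default | unit | rationale |
|---|---|---|---|
| contrast p | < 0.008 | probability | Bonferroni over 6 contrasts at 0.05 |
| median per-donor fold change | > 2 or < 1/2 | linear-scale ratio | biologically meaningful effect size |
| median per-donor absolute difference | > 150 | intensity units | guards against high ratios at noise-level baselines |

Two deliberate interpretations: *down*-regulation is median FC < 1/2
(the symmetric reciprocal of the stated up form), and the median is taken
over the per-subject ratios (not a ratio of medians), following the
literal "median of fold changes of the subjects" reading. Fold changes
and differences are always computed on the **linear** intensity scale,
while the ANOVA runs on log2 — log transformation stabilizes the variance
for the model fit, but the difference filter is only meaningful in
original intensity units. An intensity floor (default 1.0, configurable)
is applied at load so ratios are always defined.

## Degenerate inputs

With MSE = 0 (noiseless fixtures) the contrast convention is p = 0 when
the estimate is nonzero and p = 1 otherwise, so exact synthetic worlds
remain testable rather than erroring. An even number of blocks makes the
median the mean of the two central order statistics; as a consequence the
reciprocity `median_fc(A,B) = 1/median_fc(B,A)` is exact only for odd
block counts (the test suite asserts the exact form at b = 7).

# The synthetic-data generator

`simulate_expression()` draws

$$\mathrm{intensity}(g,d,j,r) = 2^{\,\mu_g + \beta_d + \tau_{gj} + \varepsilon}$$

with $\mu_g \sim N(9, 1.5^2)$ (log2 baseline: median ≈ 512 intensity
units, so a planted 3-fold change clears the 150-unit difference filter
for typical genes), $\beta_d \sim N(0, 0.3^2)$ a per-donor block effect
shared across genes, $\tau_{gj}$ the planted class effect (additive on
log2, shared across donors — matching the model's no-interaction
assumption), and per-measurement noise
$\varepsilon \sim N(0, \sigma^2_{noise} + \sigma^2_{rep})$ with defaults
0.15 and 0.10 (log2). Defaults: 8 donors, duplicate arrays, 14,500 genes;
`n_genes` scales down with the default effect-class palette rescaled
proportionally.

The default palette mirrors the Venn-region archetypes of this design —
combination-unique up (97 of 14,500), IgG-shared up (133), IL12-shared up
(16), up in all three (4), combination-unique down (164), IgG-shared down
(51), remainder null — with planted magnitude 3-fold (log2 3), above the
2-fold calling threshold but realistic for cytokine-response genes. The
reported per-region counts for this design are internally inconsistent
for one marginal total; the generator follows the per-region values and
lets marginals be their sum.

All draws come from one explicitly seeded Mersenne–Twister stream
(inversion normals, rejection sampling) in a fixed order — gene
baselines, donor effects, residual matrix — so outputs are bit-identical
across platforms and sub-simulations are independently reproducible.

**What a green test establishes — and does not.** The generator produces
exactly the world the model assumes: log-normal intensities, additive
block effects, no gene–gene correlation, no probe-level artifacts, no
intensity-dependent variance, no outlier arrays. Recovery and calibration
results on it validate the *implementation*, not the model's adequacy for
real arrays. Replicate concordance of the default world is r² ≈ 0.95–0.99
depending on gene count and baseline spread; real-array duplicate r² can
be higher because array-wide dynamic range dominates the correlation.

`simulate_annotations()` plants categories drawing a stated fraction of
members from a named truth class (the in-class count is deterministic,
`round(fraction × size)`, so a background-rate category concentrates its
enrichment p near the null value rather than spreading uniformly — the
substantive property, no spurious enrichment, is what the suite tests).
`simulate_network()` plants a bridge motif (two random directed clusters
joined only through one bridge node, which therefore carries every
inter-cluster shortest path), a hub/authority motif (a dense bipartite
block over sparse background), or both; in the combined motif the bridge
attaches through two gateway nodes per cluster so that it stays
spectrally light and the bipartite block dominates the HITS principal
component, while still carrying all inter-cluster paths.

# Set analysis and clustering

`venn_partition()` is exact set algebra over the seven regions, with the
conservation identities (disjointness, coverage,
|A| = |A-only| + |AB| + |AC| + |ABC|) property-tested on random triples.
`hierarchical_cluster()` mean-centers each gene's log2 profile across
samples — the display semantics of the usual heat map — then clusters
genes and samples agglomeratively. Default distance is correlation
(1 − Pearson) with average linkage; Euclidean/complete are available to
mirror common heat-map defaults, since the original tool parameters are
unstated. A zero-variance profile receives the maximal correlation
distance 2.0 with a warning. Ties are resolved by `stats::hclust`'s
deterministic agglomeration; no optimal-leaf-ordering is applied
(determinism over aesthetics).

# Enrichment and augmentation

The overrepresentation statistic is the one-sided hypergeometric upper
tail (equivalently one-sided Fisher), with BH adjustment across the
tested categories (those with k ≥ 1). The universe is the annotation
catalog intersected with the genes on the analyzed matrix. Defaults
q < 0.05 and k ≥ 2 select the categories whose members augment the
differential seed (`augment_gene_set()`, cap default 500, truncation in
category-then-gene-id order, provenance recorded). These thresholds are
package defaults, not reproductions: the original analysis named a tool
but no statistic or cutoffs.

# Network centrality

Arcs are directed; undirected input rows expand to two opposing arcs, and
parallel arcs aggregate by weight sum. Shortest paths are **unweighted**
(hop count): no weighted-path semantics were defined for this analysis,
and hop-based BC is the convention of the network tool referenced.
Betweenness uses Brandes' dependency accumulation, normalized by
(n−1)(n−2) on the directed graph so scores lie in [0, 1]; graphs with
fewer than 3 nodes score zero, and disconnected pairs simply contribute
nothing. HITS runs on the 0/1 adjacency by default (weighted optional),
uniform positive start, per-iteration L2 normalization, tol 1e-8, at most
1000 iterations — deterministic by construction and checked against dense
eigendecompositions of AAᵀ/AᵀA. Rank ties break lexicographically by gene
identifier. Whether the original BC was computed on the directed or
symmetrized graph, and whether edge weights entered it, is unstated;
directed/unweighted are this package's defaults and both choices are
surfaced as options rather than silently assumed.

# Pipeline and numerical conventions

`run_pipeline()` persists every intermediate table (TSV, UTF-8, '.'
decimal separator, `NA` missing token), writes a Pajek `.net` export of
the final network, and emits `report.json` with md5 checksums, stage
counts, and top-20 BC / top-9 hub / top-9 authority tables (the
conventional report shape for this analysis; sizes configurable).
`summarize_report()` re-reads outputs and fails loudly on checksum or
count mismatches. Configuration is JSON (the environment provides a JSON
parser but no YAML parser; same structure, different serialization). All
stages are runnable standalone through the CLI subcommands.

# Known limitations

- The replicate-collapse rule (arithmetic mean in linear scale) is a
  design choice; the original analysis entered one profile per donor per
  condition without stating the rule. The uncollapsed study is kept
  available for sensitivity checks.
- Whether the original ANOVA ran on log or linear intensities is
  unstated; this package fits on log2 (flagged for sensitivity analysis
  via `log2_transform = FALSE`).
- No moderated-variance or mixed-model alternatives; Bonferroni only
  (the filter is reproduced as printed, not improved).
- Enrichment does not propagate annotations up an ontology graph and does
  not implement any tool-specific adjusted score.
- The centrality machinery reproduces rankings on *given* edge tables; it
  does not infer functional linkages.
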