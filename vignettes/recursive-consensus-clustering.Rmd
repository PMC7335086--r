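---
title: "Recursive consensus clustering: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recursive consensus clustering: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcclust)
```

## The model

`rcclust` treats cluster discovery in a transcriptome matrix as a
recursive decision problem. A node of the recursion holds a set of
samples; the question at each node is not "what is the best partition?"
but "is there a partition supported strongly enough to be believed, and
if so into how many parts?" Three kinds of evidence answer it:

* **Consensus stability.** Repeated k-means on random subsets of samples
  (pItem) and genes (pFeature) yields, for every sample pair, the
  fraction of co-draws in which the pair co-clustered, scaled to an
  integer consensus index 0–100. A believable k produces a bimodal index
  (pairs are together always or never); an over- or under-split produces
  intermediate values. The empirical CDF of the index summarizes this:
  for a perfect clustering it is flat at the between-pair fraction
  (the perfect-CDF value) from c = 0 to c = 99. The flatness and span of
  the CDF around that plateau — fitted as a line, trimmed from the
  unstable low-c end — give two acceptance statistics (length, slope).
* **Partition coherence.** The mean consensus within clusters
  (intra-cluster stability, want > 0.8) and between clusters
  (inter-cluster overlap, want < 0.2) of the candidate partition.
* **Biological validity.** k-means happily splits asymmetric noise, so a
  candidate partition must also show differential expression: more than
  a minimum fraction of the node's genes significantly upregulated
  (one-vs-rest Wilcoxon, BH FDR < 0.01) in at least one cluster. This is
  the criterion that makes structureless data terminate.

Eight consensus processes with different (pItem, pFeature) settings vote;
the most frequent per-process best k wins. A zero vote, or a node smaller
than the minimum sample count, ends the branch. Because each node
re-selects its most variant genes, a level-1 split driven by strong
global markers does not mask sub-structure: inside a level-1 cluster
those markers are flat and the next tier of variance takes over.

Input assumptions: the matrix is normalized and log2(x+1)-transformed
upstream (the loader validates finiteness and only warns when values look
unlike log2 data); columns are samples/cells, rows are genes; attributes,
gene sets, and survival tables are optional side inputs.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `min_slope_deg` | 10 | degrees | max CDF line slope (criterion b); lower = tighter |
| `min_line_length` | 30 | consensus-index units | min CDF line span (criterion a); perfect = 99 |
| `intra_stability_min` | 0.8 | fraction | criterion c |
| `inter_overlap_max` | 0.2 | fraction | criterion d |
| `min_de_pct` | 10 (N ≤ 1000) / 20 | percent | criterion e, resolved from dataset size |
| `variant_gene_pct` | 3 (bulk) / 1 (single-cell) | percent | per-node feature selection |
| `bulk_min_features` | 500 | genes | feature floor, bulk only |
| `min_samples` | 20 | samples | node size below which recursion stops (strict <) |
| `repeats_per_process` | 100 | repeats | consensus repeats per process |
| `weight_slope_deg`, `weight_line_length` | 5, 40 | deg, units | tie-break weights among passing ks |
| `marker_fdr`, `marker_lfc` | 0.01, 1.0 | — , log2 | marker-gene thresholds |

Degree thresholds are only meaningful on a symmetric axis scale, so all
line geometry lives on 0–100 × 0–100 (c = 0..99 versus 100·CDF): the
±0.5 band allowance and the 10°/5° thresholds are interpreted there. On
the raw [0,1] CDF scale a 10° slope could never be reached.

## Numerical choices

* **z-scaling** uses the sample (n−1) standard deviation, matching the
  default of `var()`/`sd()`. Variance ties in feature selection break by
  gene id so runs are reproducible under permutation.
* **Line trimming** removes points from the low-c end of the band: CDF
  curves rise steeply at low consensus indices (unstable pairs) while the
  plateau extends to c = 99, so trimming low-c preserves the "ends at 99"
  geometry. Trimming stops when the slope passes or the remaining span
  drops below `min_line_length`; a band with fewer than two integer c
  values is an invalid fit (the k simply fails criteria a/b).
* **Consensus labels** for a candidate k come from average-linkage
  hierarchical clustering of `1 − index/100` cut at k — the conventional
  way to read a partition out of a consensus matrix.
* **The k-means engine.** The consensus loop runs ~7200 k-means calls per
  node vote (8 processes × 100 repeats × k = 2..10). The package runs
  this loop in compiled code: Lloyd iterations with BLAS-computed
  distances, k-means++ seeding, a single start per repeat, and an
  iteration cap of 50 with early stopping on a stable assignment.
  k-means++ seeding makes single starts reliable, and the consensus over
  100 subsampled repeats — not restart multiplicity — is the averaging
  mechanism of the method. The user-facing `kmeans_labels()` keeps the
  classical Hartigan–Wong path (`stats::kmeans`), and the test suite
  asserts that the engine's consensus labels agree (ARI = 1) with a
  1000-restart Hartigan–Wong oracle on separable data. Within a process,
  each repeat draws one sample/feature subset and clusters it at every k,
  so the co-drawn counts are shared across k.
* **Degenerate draws**: a subsample with fewer distinct points than k is
  redrawn (up to 10 times) when the subsample is small enough for that to
  be plausible (m < 3k); empty clusters during Lloyd iterations reseed at
  a random point.
* **Rank-sum tests** (criterion e and markers) use the normal
  approximation with tie and continuity corrections, vectorized across
  genes with ranks computed once per node; `wilcox.test(exact = FALSE)`
  is the reference implementation the tests compare against. Fold changes
  are differences of means on the already-log2 input scale.
* **Vote ties** break toward the smaller k: the coarser split keeps the
  recursion meaningful (the finer structure can still be found one level
  down). The partition realizing the voted k is taken from the process
  whose best set contains it with the longest, then flattest, line.
* **ssGSEA** uses the integrated running-sum statistic with rank-weight
  exponent 0.25; per-set scores are z-scored across samples only for the
  heatmap.
* **Seeding**: one top-level seed drives everything; the eight process
  seeds are drawn from it, and each process seeds R's RNG (which also
  drives the compiled engine) independently, so results do not depend on
  execution order.

## What the synthetic generator emulates — and what it does not

`simulate_flat()` draws a per-gene baseline from Normal(5, 1), adds a
disjoint block of `markers_per_group` genes upregulated by `effect_log2`
per group, and Normal(0, `noise_sd`) noise; `simulate_nested()` layers
super-group blocks (effect 8) over disjoint sub-group blocks (effect 2,
a 4:1 ratio) so that global variance is dominated by the super-group
markers — the situation that makes per-node feature re-selection
necessary. Validation scales are 5 × 50 samples × 2000 genes (equal
design), (100, 60, 40, 30, 20) (unequal design), and (60, 60)/(40, 40,
40) nested; these sizes make a full node vote a seconds-scale operation
while keeping every sub-group clusterable (n ≥ 20, maxK ≥ true k).

The generator is deliberately not a realistic scRNA-seq simulator: no
library-size variation, batch effects, dropout-rate/expression coupling
(an optional hard dropout threshold exists), or UMI noise. Passing tests
therefore demonstrate the correctness of the algorithm's decision logic
on separable log-scale data — they do not certify performance on real
single-cell data, where normalization quality and marker sparsity
dominate.

## Known limitations

* k-means geometry: clusters are assumed roughly isotropic in the
  z-scored selected-feature space; elongated or manifold-shaped
  populations can be split along their length.
* maxK = min(10, N/10) bounds discoverable structure per level; more than
  10 groups must emerge over multiple levels.
* The DE validity criterion needs clusters of at least 2 samples and
  loses power for very small clusters near the `min_samples` boundary.
* No re-merging: an early over-split cannot be undone at deeper levels
  (the level cutoff only truncates depth).
* Fisher enrichment reports raw and BH-adjusted p per (cluster, value)
  pair; with many attribute levels the adjusted values are conservative.

## A small end-to-end run

```{r example, eval = FALSE}
sim <- simulate_flat(seed = 7)
tree <- rcc_run(sim$X, rcc_config("bulk", seed = 11))
tree_summary(tree)
adjusted_rand_index(tree$final, sim$labels)  # 1 on this fixture

mk <- tree_markers(sim$X, tree)
tracking_plot(tree, mk, annotation = NULL, "trackingPlot.pdf")
```
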