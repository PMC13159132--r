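---
title: "Permutation-based cell typing and per-cell attributes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation-based cell typing and per-cell attributes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permtyper)
```

## What this package computes

permtyper annotates droplet scRNA-seq cells against a curated marker
panel using a per-cell permutation test, computes per-cell quality and
inequality attributes, and calls type-specific genes and condition DEGs
with fixed-threshold criteria. It was built around the analysis of a
hypoxia-exposed rat testis dataset — germ-cell stages from spermatogonia
through elongating spermatids plus somatic types — but every stage is
generic over the marker panel and condition labels.

All thresholds below are package defaults, chosen to match the analysis
the package reimplements; each is a visible parameter.

## Preprocessing model

Starting from a cells-by-genes UMI matrix, cells with fewer than 500
detected genes (count > 0) and genes detected in 10 or fewer cells are
removed — the cell rule is inclusive ("at least 500"), the gene rule
strict ("more than 10"). The cell filter is applied first, on the input
matrix, then the gene filter once on the cell-filtered matrix; one pass
each, no iteration. Iterating the two rules to a fixed point can cascade
(removing genes lowers per-cell detection), and the single ordered pass
is deterministic and easy to report, so `filter_cells_genes()` does
exactly that and records what it removed.

Expression is normalized per cell by the median-ratio rule: each cell's
counts are divided by `total_c / median(totals)`, so after scaling every
cell's total equals the median raw total exactly (checked to 1e-9
relative tolerance in the tests), then transformed `log2(x + 1)`. The
median is the standard midpoint median. "Total reads" is interpreted as
total UMIs — the platform counts deduplicated molecules. All downstream
scoring uses these log2 values; only the chromosome-class fractions and
library sizes use raw counts, because they are defined in UMI units.

## The typing statistic

For a cell with expression vector $x$ and a type with $k$ markers, the
observed statistic is the mean expression of the markers. The null is
built by drawing $k$ genes uniformly **without replacement** from the
cell's own expression vector, 1000 times; this preserves the cell's
value distribution exactly, which matters because per-cell distributions
differ strongly (a spermatid's transcriptome is far more concentrated
than a spermatogonium's). Then

* enrichment score: `ES = mean(markers) / mean(background means)`
* empirical FDR: fraction of background means **strictly** greater than
  the observed mean.

With 1000 permutations the FDR is a multiple of 0.001, so the criterion
`FDR < 0.001` is satisfiable only by zero exceedances — a documented
consequence of the permutation count, not a bug. A type is a candidate
when more than 20% of its markers are detected, FDR < 0.001 and ES ≥ 5;
the candidate with the highest ES wins. A 500-gene negative control set,
drawn once per run from genes outside every marker list and shared by
all cells (so control scores are comparable across cells), guards
against cells that score high on any random gene set: if the winning
type's ES falls below the control ES the cell is labelled
`random_others`; with no candidates it is `no_type_match`.

Degenerate cases are handled by sentinel, never silently: a zero
background mean with positive observed mean gives `ES = Inf` (passes),
zero observed with zero background gives `ES = 0` (fails), so an empty
cell can never be typed.

The removal of labelled cells that sit apart from their type in the 2-D
embedding — originally a visual step — is made explicit by
`consistency_filter()`: each type's cells are density-clustered in the
embedding and cells outside the type's largest cluster, or inside a
cluster whose majority label differs, are flagged (never removed; that
is the caller's decision). Types smaller than `min_cluster_size` are
left unflagged, since a handful of cells cannot evidence a spatial
cluster. This is an interpretation: it trades the original's judgement
for reproducibility.

## Per-cell attributes

* **Gini index** over the cell's expressed (positive) normalized values,
  with the order-statistic estimator
  $G = \frac{1}{n}(n+1-2\sum_i (n+1-i) y_i / \sum_i y_i)$,
  $y$ ascending, no small-sample correction. It is algebraically half
  the relative mean absolute difference, and the tests enforce that
  identity to 1e-12 against an independent brute-force oracle.
* **chrM%/chrX%/chrY%**: percentages of raw UMIs on each chromosome
  class. The class sizes (e.g. 13 mitochondrial genes in the original
  annotation) are data, not constants: the annotation table supplies
  them.
* **UMI(log10)** and the detected-gene count.
* **Diversity**: 1 minus the mean Pearson correlation between a cell and
  every other cell of its type, reported per cell (a singleton type has
  no defined diversity; zero-variance profiles are excluded from the
  mean, with a message). Values near 0 mean a homogeneous type; i.i.d.
  noise gives values near 1.

`attribute_gene_correlation()` correlates one gene's expression with an
attribute **restricted to the cells expressing the gene**, per type and
pooled — the design used to show that a repressor's expression
anti-correlates with how many genes a cell expresses. A constant vector
yields `NA`, never a silent zero.

## Marker and DEG callers

Both callers use the classic pooled-variance two-sided Student t-test —
the named reference implementation's default — vectorized over genes,
with zero-variance groups resolved by sentinel (equal means: p = 1;
unequal: p = 0). Fold changes are differences of group means of the
already-log2 values; no pseudocount is added because the data are
already on the log scale.

Type-specific genes must satisfy five criteria evaluated independently
(each flag is reported): detection in ≥ 20% of the type's cells; a
detection-rate difference of ≥ 10 percentage points over the rest;
p < 1e-10; log2 fold change ≥ 2; overall mean above the median of all
genes' overall means. The detection criterion's source wording ("≥10% of
the genes were detected for the given cell types vs. others") is
ambiguous; the difference reading is the default and the alternative
("detected in ≥10% of all cells") is available as
`detection_rule = "overall"`. Condition DEGs within a type use p <
1e-10, |log2FC| ≥ 1 (the fold-change sign is reported as the direction
in the second condition) and the same overall-mean criterion. No
multiple-testing correction is layered on top: the method is a fixed
threshold, not an FDR procedure.

## The synthetic testis generator

`simulate_dataset()` draws UMI counts from a negative binomial with
shared size parameter 2 (a standard droplet noise model), lognormal gene
base means (meanlog log 0.5, sdlog 1), and per-cell lognormal library
factors (sdlog 0.3). Each of five default types (spermatogonia,
spermatocytes, round and elongating spermatids, Sertoli) gets 10 planted
markers elevated 2^3-fold in its own type; 200 cells per type and
condition. Genes are tagged MT/X/Y/AUTO (MT base means boosted 5-fold —
mitochondrial transcripts are abundant). The hypoxia condition applies
planted effects (Asxl2-like, log2 fold −2; Cep162-like, +2) in the
spermatid stages, and an optional coupling multiplies the Asxl2-like
gene's mean by `(mean_library/library)^1.5`, planting the negative
expression-vs-detected-genes dependence the attribute correlation is
meant to find. Doublets (default 5% of cells) are negative-binomial
draws around the scaled sum of two same-condition type profiles at 1.4x
the mean library — intermediate profiles that stress the typing
criteria. `testis_composition()` encodes the reported composition shift
(elongating 50.397% → 42.386%, round 8.831% → 11.215%) as fixed
per-condition counts so that a planted shift is exactly known.

Two generator choices deserve justification because they interact with
the analysis scale:

* Marker and planted-effect genes are given moderately high base
  expression (marker base means lognormal(log 2.5, 0.3), effect genes
  base mean 4). On the `log2(x+1)` scale the expected value of a
  negative-binomial gene compresses fold changes at low means (measured:
  mean 0.5 → 0.43 log2 units, 4 → 1.97, 16 → 3.7, 32 → 4.6), so an
  8-fold marker in a gene with mean 0.5 cannot carry the 2 log2 units
  the marker caller demands. Real curated markers are robustly expressed
  transcripts, so this is realism, not convenience.
* Marker base means are capped at 3 UMIs (`marker_base_max`). A gene
  whose baseline puts it in more than ~90% of all cells fails the
  detection-difference criterion by construction — it is not a marker in
  the method's own sense — and real panels screen such genes out. The
  cap keeps the planted truth self-consistent with the marker
  definition.

What the generator does **not** model: batch effects beyond the
condition, ambient RNA, gene–gene correlation beyond the type structure,
zero inflation beyond the negative binomial, and continuous
developmental trajectories (types are discrete). Passing tests therefore
demonstrate that the pipeline recovers planted structure under its own
statistical assumptions, not that it resolves the harder features of
real testis data (e.g. the continuum between consecutive spermatid
stages).

## Embedding and density clustering

Embedding and subtype clustering are published algorithms this package
merely parameterizes, so they are pluggable backends behind a thin
contract. `embed_cells()` drives uwot's UMAP with the standard
parameters (n_neighbors 100, 2 components, min_dist 0, random
initialisation, Euclidean metric, random state 123, 1000 epochs),
single-threaded for exact reproducibility; `min_dist = 0` is nudged to
1e-9 because the backend's curve fit requires a positive value, which is
numerically indistinguishable. Density clustering
(`density_cluster()`) joins points within `eps` of each other over a
k-nearest-neighbour graph and takes connected components, discarding
components below `min_cluster_size` (default 100) as noise; `eps`
defaults to 3x the 98th percentile of the 10th-NN distance, forgiving
enough to keep a region's tail points attached while leaving separated
regions apart. This is a deliberately simple stand-in for hierarchical
density clustering: it has one scale rather than a hierarchy, so it will
merge nested density levels that HDBSCAN would split. `eps` and the
backend are both configurable.

## Determinism and problem sizes

One master seed drives the generator, the negative-control draw, every
permutation and the embedding random state; re-running a pipeline
configuration reproduces byte-identical TSVs and manifest
(`run_pipeline()` writes both, plus a log with per-stage timings that is
deliberately excluded from the comparison). The test suite runs its
end-to-end checks on a 360-cell, 400-gene miniature (base expression
lowered to keep the marker-to-background contrast representative at that
size) and the statistical guarantees (null label rate ≤ 1%, ≥ 95%
planted-label recovery, caller precision/recall ≥ 0.9, t-test
calibration, composition-shift direction over 20 seeds) at the
generator's default 2000-cell scale — sizes chosen so the whole suite
runs in minutes while keeping each check adequately powered.

## Known limitations

* The permutation null treats genes as exchangeable within a cell;
  correlated marker sets (co-regulated genes) make the ES slightly
  anti-conservative.
* `FDR < 0.001` with 1000 permutations is an exact-zero criterion; users
  wanting finer granularity must raise `n_perm` (cost is linear).
* The density backend is single-scale (see above).
* The consistency filter depends on the embedding; a poor embedding
  flags good cells. Flags are advisory for exactly this reason.
* The t-test operates on log-normalized values and inherits the usual
  caveats of normal-theory tests on sparse counts; the extreme p
  threshold (1e-10) makes the callers robust to moderate miscalibration,
  which the null-calibration test quantifies.
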