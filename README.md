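# permtyper

Marker-based cell typing for droplet single-cell RNA-seq with a per-cell
permutation test, plus the per-cell attributes and fixed-threshold gene
callers that go with it.

## The problem

Continuous developmental tissues such as testis do not fall into crisp
clusters: spermatogonia, spermatocytes, round spermatids and elongating
spermatids form one long trajectory, and cluster-then-annotate
workflows struggle at the boundaries. An alternative is to score every
cell directly against a curated marker panel. For a cell with
normalized expression $x$ and a type with $k$ marker genes:

* **ES** (enrichment score) — the mean marker expression divided by the
  mean of 1000 random background means, each the average of $k$ genes
  drawn without replacement from the cell's own expression vector;
* **FDR** (empirical, per cell) — the fraction of those 1000 background
  means strictly above the observed marker mean.

A type is assigned when more than 20% of its markers are detected,
FDR < 0.001 and ES ≥ 5; among several candidates the highest ES wins. A
500-gene random negative control guards against promiscuous cells
(`random_others` when the control outscores the best type), and cells
matching nothing are `no_type_match`. A density-clustering consistency
filter flags labelled cells that sit apart from their type in the 2-D
embedding.

Around that core the package provides: 10x-style MatrixMarket I/O;
cell/gene detection filtering (≥ 500 genes per cell, > 10 cells per
gene) and median-ratio `log2(x+1)` normalization; per-cell attributes
(Gini index of expression inequality, chrM%/chrX%/chrY% UMI fractions,
UMI(log10), detected genes, within-type diversity = 1 − mean Pearson
correlation); a five-criterion cell-type-specific gene caller and a
three-criterion condition DEG caller on the pooled Student t-test; a
negative-binomial testis simulator with planted ground truth (markers,
composition shifts, condition effects, doublets); and a seeded pipeline
driver with pluggable UMAP/density-clustering backends.

## Worked example

Simulate a testis-like dataset (five cell types, two conditions, 5%
doublets), preprocess, type every cell and call markers and DEGs:

```r
library(permtyper)

sim      <- simulate_dataset(simulation_config(), seed = 42)
filtered <- filter_cells_genes(sim$matrix)   # >=500 genes/cell, >10 cells/gene
nm       <- normalize_counts(filtered)       # median-ratio, log2(x+1)
typing   <- assign_cell_types(nm, sim$panel, seed = 43)
table(typing$label)
#> elongating_spermatids         no_type_match      round_spermatids
#>                   404                    74                   411
#>               sertoli         spermatocytes         spermatogonia
#>                   417                   402                   387
```

2100 cells were generated (400 per type plus 100 doublets), 5 were
removed by the detection filter, and 98.3% of the remaining singlets
received their planted label; the 74 `no_type_match` cells are mostly
doublets and cells whose enrichment score fell just under the ES ≥ 5
threshold. Marker calling on the typed cells recovers the planted
elongating-spermatid markers:

```r
markers <- specific_genes(nm, typing$label, "elongating_spermatids")
head(markers[markers$passes, c("gene_id", "p_value", "log2fc", "pct_in")], 4)
#>                      gene_id       p_value   log2fc    pct_in
#> 31                      Prm2 5.445491e-268 2.280103 0.9752475
#> 32                    Dnmt3l 1.092504e-289 2.413083 0.9925743
#> 33 elongating_spermatids_m01 1.151954e-288 2.346692 0.9801980
#> 34 elongating_spermatids_m02 9.904360e-311 2.642867 1.0000000
```

and the DEG caller finds exactly the two planted hypoxia effects in
round spermatids, with the right directions:

```r
degs <- condition_degs(nm, typing$label, "round_spermatids",
                       "normoxia", "hypoxia")
degs[degs$passes, c("gene_id", "p_value", "log2fc", "direction")]
#>    gene_id      p_value    log2fc direction
#> 51   Asxl2 4.976530e-31 -1.331096      down
#> 52  Cep162 5.864885e-51  1.814870        up
```

`p_value` is the pooled two-sided Student t-test; `log2fc` is the
difference of mean log2 expression (condition_b minus condition_a), so
−1.33 means a ~2.5-fold drop on the normalized scale.

`run_pipeline(pipeline_config(seed = 1), "out/")` chains all stages
(simulate/read → filter+normalize → embed → type → consistency filter →
attributes → markers → DEGs → subtypes) and writes one TSV per stage
plus a JSON manifest; the same seed and configuration reproduce the
outputs byte for byte.

## Documentation

The methods vignette (`vignettes/permutation-cell-typing.Rmd`) explains
the statistical model, every default threshold, the generator's design
and what the synthetic benchmarks do and do not demonstrate. All
exported functions carry full roxygen documentation.
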