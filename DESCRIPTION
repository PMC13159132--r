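Package: permtyper
Title: Permutation-Based Marker Cell Typing and Per-Cell Attributes for
    Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Marker-panel cell-type annotation for droplet single-cell
    RNA-seq using a per-cell permutation enrichment score with an empirical
    false discovery rate, a random-gene negative control and a
    spatial-consistency filter; per-cell quality and inequality attributes
    (Gini index of expressed-gene expression, chromosome-class UMI
    fractions, library size, within-type diversity); threshold-based
    cell-type-specific gene and condition differential-expression callers
    built on the pooled two-sample Student t-test; and a negative-binomial
    testis-like count simulator with planted ground truth so the whole
    pipeline is testable end to end. Includes 10x-style MatrixMarket
    input/output, median-ratio normalization, and a seeded, manifest-logged
    pipeline driver with pluggable embedding and density-clustering
    backends.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    RANN,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    uwot,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
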