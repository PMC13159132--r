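# Shared fixtures built in code.

# Small, fast simulation: 3 types x 60 cells x 400 genes, no doublets.
# With only 400 genes the planted markers would be a larger share of the
# expression background than at full scale, so the base expression is
# lowered to keep the fixture's marker-to-background contrast
# representative of the full-size default.
small_sim_config <- function(doublet_rate = 0,
                             n_cells_per_condition = list(
                               normoxia = c(spermatocytes = 60,
                                            round_spermatids = 60,
                                            elongating_spermatids = 60),
                               hypoxia = c(spermatocytes = 60,
                                           round_spermatids = 60,
                                           elongating_spermatids = 60)),
                             ...) {
  simulation_config(
    types = c("spermatocytes", "round_spermatids", "elongating_spermatids"),
    n_cells_per_condition = n_cells_per_condition,
    n_genes = 400L,
    base_expression = c(meanlog = log(0.2), sdlog = 1),
    doublet_rate = doublet_rate,
    ...)
}

# Write a hand-sized MTX bundle and return its paths.
write_micro_bundle <- function(dir = withr::local_tempdir(
                                 .local_envir = parent.frame())) {
  fx <- micro_fixture()
  write_matrix(fx$matrix, dir)
  list(dir = dir,
       mtx = file.path(dir, "matrix.mtx"),
       barcodes = file.path(dir, "barcodes.tsv"),
       features = file.path(dir, "features.tsv"),
       annot = file.path(dir, "annotation.tsv"),
       conditions = file.path(dir, "conditions.tsv"),
       fixture = fx)
}

# Independent Gini oracle: half the relative mean absolute difference,
# G = sum_ij |y_i - y_j| / (2 n^2 ybar).
gini_mad_oracle <- function(y) {
  n <- length(y)
  sum(abs(outer(y, y, "-"))) / (2 * n^2 * mean(y))
}

# Truth rows aligned to a (possibly filtered) matrix.
aligned_truth <- function(sim, obj) {
  sim$truth$cells[match(obj$barcodes, sim$truth$cells$barcode), ]
}

# Bare NormalizedMatrix for constructed boundary cases.
make_nm <- function(values, condition = rep(NA_character_, nrow(values)),
                    genes = sprintf("g%03d", seq_len(ncol(values))),
                    barcodes = sprintf("c%03d", seq_len(nrow(values)))) {
  dimnames(values) <- list(barcodes, genes)
  structure(list(values = values, scale_factors = rep(1, nrow(values)),
                 median_total = 1, barcodes = barcodes, genes = genes,
                 chrom_class = rep("AUTO", ncol(values)),
                 condition = condition, symbols = genes,
                 layer = "normalized"),
            class = "NormalizedMatrix")
}
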