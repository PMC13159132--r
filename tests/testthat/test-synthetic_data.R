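test_that("simulation is byte-reproducible from its seed", {
  cfg <- small_sim_config()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(simulate_dataset(cfg, seed = 81), d1)
  write_simulation(simulate_dataset(cfg, seed = 81), d2)
  for (f in c("matrix.mtx", "barcodes.tsv", "features.tsv",
              "annotation.tsv", "conditions.tsv", "ground_truth.tsv",
              "gene_truth.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = f)
  # a different seed changes the data
  s3 <- simulate_dataset(cfg, seed = 82)
  expect_false(identical(as.matrix(s3$matrix$counts),
                         as.matrix(simulate_dataset(cfg, 81)$matrix$counts)))
})

test_that("doublet bookkeeping and planted composition are exact", {
  sim0 <- simulate_dataset(small_sim_config(), seed = 83)
  expect_identical(sum(sim0$truth$cells$is_doublet), 0L)

  cfg <- small_sim_config(doublet_rate = 0.1)
  sim <- simulate_dataset(cfg, seed = 84)
  tc <- sim$truth$cells
  expect_equal(sum(tc$is_doublet), round(0.1 * sum(!tc$is_doublet)))
  expect_true(all(grepl("\\+", tc$constituents[tc$is_doublet])))
  # singlet composition equals the configured counts exactly
  sing <- tc[!tc$is_doublet, ]
  for (cond in names(cfg$n_cells_per_condition))
    for (t in cfg$types)
      expect_equal(sum(sing$condition == cond & sing$true_type == t),
                   unname(cfg$n_cells_per_condition[[cond]][[t]]))
  # matrix and truth stay aligned
  expect_identical(tc$barcode, sim$matrix$barcodes)
  expect_identical(tc$condition, sim$matrix$condition)
})

test_that("planted marker fold is realized in the counts", {
  sim <- simulate_dataset(simulation_config(doublet_rate = 0), seed = 85)
  counts <- as.matrix(sim$matrix$counts)
  tc <- sim$truth$cells
  gt <- sim$truth$genes
  folds <- c()
  for (t in unique(gt$marker_of[!is.na(gt$marker_of)])) {
    gidx <- which(gt$marker_of %in% t)
    in_cells <- tc$true_type == t
    folds <- c(folds, log2(colMeans(counts[in_cells, gidx]) /
                           colMeans(counts[!in_cells, gidx])))
  }
  expect_lt(abs(mean(folds) - sim$config$marker_log2_fold), 0.3)
})

test_that("gene truth records markers, chromosome classes and effects", {
  sim <- simulate_dataset(small_sim_config(), seed = 86)
  gt <- sim$truth$genes
  expect_identical(gt$gene_id, sim$matrix$genes)
  expect_identical(gt$chrom_class, sim$matrix$chrom_class)
  expect_equal(sum(!is.na(gt$marker_of)),
               3L * sim$config$n_markers_per_type)
  expect_setequal(gt$gene_id[gt$condition_log2_fold != 0],
                  c("Asxl2", "Cep162"))
  # panel matches the planted truth
  for (t in sim$panel$types)
    expect_setequal(sim$panel$markers[[t]],
                    gt$gene_id[!is.na(gt$marker_of) & gt$marker_of == t])
})

test_that("attribute coupling plants a negative expression/n_genes correlation", {
  hits <- 0L
  for (s in 1:10) {
    sim <- simulate_dataset(small_sim_config(), seed = 100 + s)
    f <- filter_cells_genes(sim$matrix, 50, 3)
    nm <- normalize_counts(f)
    at <- cell_attributes(f, nm)
    r <- attribute_gene_correlation(nm, "Asxl2", at, "n_genes")
    hits <- hits + (r$pcc[r$stratum == "pooled"] < 0)
  }
  expect_gte(hits, 9L)
})

test_that("hypoxia-style composition preset shifts spermatid fractions", {
  comp <- testis_composition(1000)
  norm <- comp$normoxia / sum(comp$normoxia)
  hyp <- comp$hypoxia / sum(comp$hypoxia)
  expect_gt(norm[["elongating_spermatids"]], hyp[["elongating_spermatids"]])
  expect_lt(norm[["round_spermatids"]], hyp[["round_spermatids"]])
  expect_equal(norm[["elongating_spermatids"]], 0.504, tolerance = 0.01)
})

test_that("infeasible configurations are rejected", {
  expect_error(simulation_config(n_genes = 20), "exceed")
  expect_error(simulation_config(doublet_rate = 0.5), "doublet_rate")
  expect_error(simulation_config(types = "one"), "at least 2")
})
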