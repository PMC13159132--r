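test_that("pooled t-test matches stats::t.test and handles degenerate groups", {
  expect_equal(two_sided_t(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(two_sided_t(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  deg <- two_sided_t(c(0, 0, 0, 0), c(9, 9, 9, 9))
  expect_equal(deg$p_value, 0)
  expect_true(is.infinite(deg$statistic))
  expect_error(two_sided_t(1, c(1, 2)), "at least 2")

  # independent cross-check against the reference implementation
  set.seed(61)
  for (i in 1:50) {
    a <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1))
    b <- rnorm(sample(3:30, 1), sd = runif(1, 0.5, 2))
    ours <- two_sided_t(a, b)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("planted markers pass all five criteria; boundary genes fail the right one", {
  sim <- simulate_dataset(small_sim_config(), seed = 71)
  nm <- normalize_counts(filter_cells_genes(sim$matrix, 50, 3))
  truth <- aligned_truth(sim, nm)
  for (t in unique(truth$true_type)) {
    rec <- specific_genes(nm, truth$true_type, t)
    planted <- sim$truth$genes$gene_id[
      !is.na(sim$truth$genes$marker_of) &
        sim$truth$genes$marker_of == t]
    called <- rec$gene_id[rec$passes]
    expect_gte(mean(called %in% planted), 0.9)
    expect_gte(mean(planted %in% called), 0.9)
  }

  # constructed boundaries: 100 target cells, 100 others, 40 genes
  vals <- matrix(0, 200, 40)
  labs <- rep(c("T", "O"), each = 100)
  vals[1:100, 1] <- 1.9            # log2fc exactly 1.9: criterion 4 only
  vals[1:100, 2] <- 0
  vals[1:19, 2] <- 5               # detected in 19% of target cells
  vals[1:100, 3] <- 3              # a clean passing control gene
  rec <- specific_genes(make_nm(vals), labs, "T")
  g1 <- rec[1, ]
  expect_false(g1$passes)
  expect_false(g1$crit4)
  expect_true(all(unlist(g1[c("crit1", "crit2", "crit3", "crit5")])))
  expect_false(rec$crit1[2])
  expect_false(rec$passes[2])
  expect_true(rec$passes[3])
})

test_that("each marker criterion threshold is monotone in isolation", {
  sim <- simulate_dataset(small_sim_config(), seed = 72)
  nm <- normalize_counts(filter_cells_genes(sim$matrix, 50, 3))
  truth <- aligned_truth(sim, nm)
  base <- specific_genes(nm, truth$true_type, "spermatocytes")
  relaxed <- list(
    specific_genes(nm, truth$true_type, "spermatocytes",
                   min_pct_in = 0.05),
    specific_genes(nm, truth$true_type, "spermatocytes",
                   min_pct_diff = 0.01),
    specific_genes(nm, truth$true_type, "spermatocytes", max_p = 1e-3),
    specific_genes(nm, truth$true_type, "spermatocytes", min_log2fc = 0.5))
  for (r in relaxed)
    expect_true(all(r$passes[base$passes]))
})

test_that("condition DEGs recover planted effects with correct direction", {
  # the printed p < 1e-10 cutoff needs ~100+ cells per condition for a
  # 4-fold effect; the coupling noise on Asxl2 is exercised elsewhere
  sim <- simulate_dataset(small_sim_config(
    n_cells_per_condition = list(
      normoxia = c(spermatocytes = 60, round_spermatids = 120,
                   elongating_spermatids = 60),
      hypoxia  = c(spermatocytes = 60, round_spermatids = 120,
                   elongating_spermatids = 60)),
    attribute_coupling = NULL), seed = 73)
  nm <- normalize_counts(filter_cells_genes(sim$matrix, 50, 3))
  truth <- aligned_truth(sim, nm)
  dg <- condition_degs(nm, truth$true_type, "round_spermatids",
                       "normoxia", "hypoxia")
  asxl2 <- dg[dg$gene_id == "Asxl2", ]
  cep <- dg[dg$gene_id == "Cep162", ]
  expect_true(asxl2$passes); expect_identical(asxl2$direction, "down")
  expect_true(cep$passes); expect_identical(cep$direction, "up")

  # swapping the conditions negates fold changes and preserves p-values
  dg_rev <- condition_degs(nm, truth$true_type, "round_spermatids",
                           "hypoxia", "normoxia")
  expect_equal(dg_rev$log2fc, -dg$log2fc)
  expect_equal(dg_rev$p_value, dg$p_value)

  # a gene identical across conditions cannot pass
  vals <- matrix(rep(c(2, 0.5), each = 40), 40, 2)
  nm0 <- make_nm(vals, condition = rep(c("x", "y"), 20))
  d0 <- condition_degs(nm0, rep("T", 40), "T", "x", "y")
  expect_equal(d0$p_value, c(1, 1))
  expect_true(!any(d0$passes))
})

test_that("label-permuted null yields essentially no DEG calls", {
  sim <- simulate_dataset(small_sim_config(), seed = 74)
  nm <- normalize_counts(filter_cells_genes(sim$matrix, 50, 3))
  truth <- aligned_truth(sim, nm)
  set.seed(75)
  nm$condition <- sample(nm$condition)
  dg <- condition_degs(nm, truth$true_type, "spermatocytes",
                       "normoxia", "hypoxia")
  expect_lte(sum(dg$crit1), 1L)
})
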