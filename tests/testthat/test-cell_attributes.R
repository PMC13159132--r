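test_that("Gini closed forms and the mean-absolute-difference oracle agree", {
  expect_equal(gini_index(rep(3, 7)), 0)
  expect_equal(gini_index(c(0, 0, 0, 1)), 0.75)   # one-hot, (n-1)/n
  expect_equal(gini_index(c(1, 2, 3, 4)), 0.25)   # frozen from the oracle
  expect_true(is.na(gini_index(numeric(0))))
  expect_true(is.na(gini_index(c(0, 0))))
  expect_error(gini_index(c(1, -1)), "non-negative")

  set.seed(11)
  for (i in 1:200) {
    y <- rlnorm(sample(1:300, 1), 0, runif(1, 0.2, 2))
    expect_equal(gini_index(y), gini_mad_oracle(y), tolerance = 1e-12)
  }
})

test_that("Gini is scale invariant and respects Pigou-Dalton transfers", {
  set.seed(12)
  for (i in 1:50) {
    y <- rlnorm(sample(2:100, 1))
    expect_equal(gini_index(3.7 * y), gini_index(y), tolerance = 1e-12)
    # transfer mass from a smaller to a larger value: inequality rises
    o <- order(y)
    lo <- o[1]; hi <- o[length(o)]
    d <- y[lo] * runif(1, 0, 0.9)
    y2 <- y; y2[lo] <- y2[lo] - d; y2[hi] <- y2[hi] + d
    expect_gte(gini_index(y2), gini_index(y) - 1e-12)
  }
})

test_that("chromosome-class fractions are percentages that sum to 100", {
  fx <- micro_fixture()
  cf <- chrom_fractions(fx$matrix)
  expect_equal(cf$chrM_pct, fx$expected$chrM_pct)
  expect_true(all(cf$chrM_pct >= 0 & cf$chrM_pct <= 100))
  # no genes of a class -> 0, and classes partition the total
  auto_pct <- unname(100 * Matrix::rowSums(
    fx$matrix$counts[, fx$matrix$chrom_class == "AUTO"]) /
    Matrix::rowSums(fx$matrix$counts))
  expect_equal(cf$chrM_pct + cf$chrX_pct + cf$chrY_pct + auto_pct,
               rep(100, 6))
})

test_that("diversity reflects within-type correlation structure", {
  # identical cells: r = 1, diversity 0
  v <- matrix(rlnorm(40), 2, 20, byrow = TRUE)
  v[2, ] <- v[1, ]
  expect_equal(expression_diversity(v), c(0, 0))
  # perfectly anti-correlated profiles: r = -1, diversity 2
  x <- rnorm(20)
  v2 <- rbind(x, -x)
  expect_equal(unname(expression_diversity(v2)), c(2, 2))
  # singleton type undefined
  expect_true(is.na(expression_diversity(matrix(1, 1, 5))))
  # i.i.d. noise cells: expected pairwise r = 0, diversity near 1
  set.seed(31)
  reps <- replicate(20, mean(expression_diversity(
    matrix(rnorm(10 * 400), 10, 400))))
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - 1), 4 * se)
  # invariance under per-cell affine rescaling
  v3 <- matrix(rlnorm(8 * 50), 8, 50)
  v4 <- v3 * runif(8, 0.5, 2) + rnorm(8)
  expect_equal(expression_diversity(v4), expression_diversity(v3))
})

test_that("per-cell attribute table is internally consistent", {
  sim <- simulate_dataset(small_sim_config(), seed = 41)
  f <- filter_cells_genes(sim$matrix, 50, 3)
  nm <- normalize_counts(f)
  truth <- aligned_truth(sim, nm)
  at <- cell_attributes(f, nm, labels = truth$true_type)
  expect_identical(at$barcode, nm$barcodes)
  expect_equal(at$n_genes, unname(Matrix::rowSums(f$counts > 0)))
  expect_equal(at$umi_log10, unname(log10(Matrix::rowSums(f$counts))))
  expect_true(all(at$gini > 0 & at$gini < 1))
  expect_true(all(!is.na(at$diversity)))
  expect_true(all(at$diversity >= 0 & at$diversity <= 2))
})

test_that("gene-attribute correlation recovers planted dependences", {
  sim <- simulate_dataset(small_sim_config(), seed = 51)
  f <- filter_cells_genes(sim$matrix, 50, 3)
  nm <- normalize_counts(f)
  truth <- aligned_truth(sim, nm)
  at <- cell_attributes(f, nm)

  # exact negative linear function of expression -> r = -1
  gi <- match("Prm2", nm$genes)
  at_fake <- at
  at_fake$probe <- 5 - 2 * nm$values[, gi]
  rr <- attribute_gene_correlation(nm, "Prm2", at_fake, "probe")
  expect_equal(rr$pcc[rr$stratum == "pooled"], -1)

  # permuted attribute: no correlation
  set.seed(52)
  at_fake$perm <- sample(at$n_genes)
  rp <- attribute_gene_correlation(nm, "Prm2", at_fake, "perm")
  expect_lt(abs(rp$pcc[rp$stratum == "pooled"]), 0.15)

  # the planted repressor couples negatively with expressed-gene count
  rc <- attribute_gene_correlation(nm, "Asxl2", at, "n_genes",
                                   labels = truth$true_type)
  expect_lt(rc$pcc[rc$stratum == "pooled"], 0)

  # tiny strata are skipped with a warning
  labs <- truth$true_type
  labs[1:2] <- "rare"
  labs[-(1:2)] <- "common"
  expect_warning(
    attribute_gene_correlation(nm, "Prm2", at, "n_genes", labels = labs),
    "rare")
})
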