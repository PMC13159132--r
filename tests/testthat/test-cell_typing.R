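test_that("marker fraction counts detected markers", {
  expr <- c(a = 1, b = 0, c = 2, d = 0, e = 0, f = 3, g = 0, h = 0,
            i = 0, j = 0)
  expect_equal(marker_fraction(expr, names(expr)), 0.3)
  expect_equal(marker_fraction(expr, c("b", "d", "e")), 0)
  expect_equal(marker_fraction(expr, c("a", "c", "f")), 1)
  expect_error(marker_fraction(expr, character()), "empty marker set")
})

test_that("permutation background is uniform subsampling of the cell's values", {
  # degenerate constant cell: every background value equals the constant
  bg <- permutation_background(rep(2.5, 50), k = 5, n_perm = 100)
  expect_equal(bg, rep(2.5, 100))

  # determinism under the RNG seed
  x <- rlnorm(300)
  set.seed(99); b1 <- permutation_background(x, 10, 1000)
  set.seed(99); b2 <- permutation_background(x, 10, 1000)
  expect_identical(b1, b2)

  # Monte-Carlo mean matches the analytic mean of sampling without
  # replacement (the cell's overall mean), within 4 standard errors
  set.seed(7)
  x <- rlnorm(500, 0, 1)
  bg <- permutation_background(x, 12, 1000)
  se <- sd(bg) / sqrt(length(bg))
  expect_lt(abs(mean(bg) - mean(x)), 4 * se)

  expect_error(permutation_background(1:5, 6, 10), "exceeds")
})

test_that("enrichment score and empirical FDR follow their definitions", {
  expect_equal(enrichment_score(10, rep(2, 100)), 5)
  expect_equal(enrichment_score(0, rep(2, 100)), 0)
  expect_identical(enrichment_score(3, rep(0, 100)), Inf)
  expect_identical(enrichment_score(0, rep(0, 100)), 0)

  bg <- c(rep(5, 250), rep(1, 750))
  expect_equal(empirical_fdr(3, bg), 0.25)
  expect_equal(empirical_fdr(10, bg), 0)
  expect_equal(empirical_fdr(0, bg), 1)
})

test_that("exhaustive subset enumeration agrees with the permutation background", {
  fx <- micro_fixture()
  nm <- normalize_counts(fx$matrix)
  expr <- nm$values["c1", ]
  k <- 3L
  subsets <- combn(length(expr), k)
  exhaustive <- apply(subsets, 2L, function(s) mean(expr[s]))
  # mean over all k-subsets is exactly the overall mean
  expect_equal(mean(exhaustive), mean(expr))
  obs <- mean(expr[c("g04", "g05", "g06")])
  es_exact <- enrichment_score(obs, exhaustive)
  expect_equal(es_exact, obs / mean(expr))
  set.seed(3)
  bg <- permutation_background(expr, k, 4000)
  expect_lt(abs(enrichment_score(obs, bg) - es_exact), 0.05 * es_exact)
})

test_that("assignment applies the ES tie-break and the negative-control rule", {
  genes <- sprintf("g%03d", 1:200)
  panelAB <- marker_panel(
    list(typeA = genes[1:10], typeB = genes[11:20]),
    negative_control = genes[21:40])

  # both types pass; the higher-ES type wins
  expr <- setNames(c(rep(8, 10), rep(12, 10), rep(0.5, 20), rep(1, 160)),
                   genes)
  set.seed(1)
  row <- assign_cell_type(expr, panelAB)
  expect_identical(row$label, "typeB")
  expect_gt(row$es_typeB, row$es_typeA)

  # inflated control genes push the top candidate below the control ES
  panelA <- marker_panel(list(typeA = genes[1:10]),
                         negative_control = genes[21:30])
  expr2 <- setNames(c(rep(10, 10), rep(0, 10), rep(12, 10), rep(0, 170)),
                    genes)
  set.seed(2)
  row2 <- assign_cell_type(expr2, panelA)
  expect_gt(row2$es_typeA, 5)
  expect_gt(row2$control_es, row2$es_typeA)
  expect_identical(row2$label, "random_others")

  # a silent cell matches nothing
  set.seed(3)
  row3 <- assign_cell_type(setNames(rep(0, 200), genes), panelA)
  expect_identical(row3$label, "no_type_match")
})

test_that("planted cell types are recovered with zero FDR and exact granularity", {
  sim <- simulate_dataset(small_sim_config(), seed = 21)
  nm <- normalize_counts(filter_cells_genes(sim$matrix, 50, 3))
  ty <- assign_cell_types(nm, sim$panel, seed = 22, n_control = 200)
  truth <- aligned_truth(sim, nm)
  hit <- ty$label == truth$true_type
  expect_gt(mean(hit), 0.95)
  # assigned types carry a zero empirical FDR for their own markers
  fdr_own <- mapply(function(i, t) ty[[paste0("fdr_", t)]][i],
                    which(hit), truth$true_type[hit])
  expect_true(all(fdr_own == 0))
  # every reported FDR is an exact multiple of 1/n_perm
  n_perm <- attr(ty, "thresholds")$n_perm
  fdr_cols <- unlist(ty[grep("^fdr_", names(ty))])
  expect_true(all(abs(fdr_cols * n_perm - round(fdr_cols * n_perm))
                  < 1e-12))
  # determinism: identical seed and inputs give identical results
  expect_identical(ty, assign_cell_types(nm, sim$panel, seed = 22, n_control = 200))
})

test_that("raising marker expression never lowers that type's enrichment score", {
  set.seed(17)
  for (rep in 1:20) {
    expr <- rlnorm(400, 0, 1)
    markers <- sample(400, 8)
    obs1 <- mean(expr[markers])
    set.seed(1000 + rep)
    bg1 <- permutation_background(expr, 8, 500)
    boosted <- expr
    boosted[markers] <- boosted[markers] * (1 + runif(1, 0.1, 2))
    obs2 <- mean(boosted[markers])
    set.seed(1000 + rep)
    bg2 <- permutation_background(boosted, 8, 500)
    expect_gte(enrichment_score(obs2, bg2),
               enrichment_score(obs1, bg1) - 1e-12)
  }
})

test_that("consistency filter flags spatially displaced cells only", {
  set.seed(5)
  nA <- 300; nB <- 300
  emb <- rbind(matrix(rnorm(nA * 2), nA, 2),
               matrix(rnorm(nB * 2, mean = 60), nB, 2))
  labels <- rep(c("A", "B"), c(nA, nB))

  # coherent geometry: nothing flagged
  expect_true(!any(consistency_filter(labels, emb,
                                      min_cluster_size = 50)))

  # one cell of type A dropped into the pure type-B cluster
  emb2 <- emb
  emb2[1, ] <- c(60, 60)
  f2 <- consistency_filter(labels, emb2, min_cluster_size = 50)
  expect_true(f2[1])
  expect_equal(sum(f2), 1L)

  # 5% of type A displaced to a far region: exactly those are flagged
  emb3 <- emb
  moved <- 1:15
  emb3[moved, ] <- matrix(rnorm(30, mean = -80), 15, 2)
  f3 <- consistency_filter(labels, emb3, min_cluster_size = 50)
  expect_identical(which(f3), moved)

  # undersized types are left unflagged with a warning
  labs <- rep(c("A", "tiny"), c(nA + nB - 5, 5))
  expect_warning(ft <- consistency_filter(labs, emb,
                                          min_cluster_size = 50),
                 "tiny")
  expect_true(!any(ft[labs == "tiny"]))
})
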