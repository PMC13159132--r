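# Validation markers used as realistic default gene names for the planted
# panels (mouse testis lineage markers).
TESTIS_VALIDATION_MARKERS <- list(
  spermatogonia = c("Ina", "Jmjd1c", "Brd4", "Rest", "Ezh1", "Tet3",
                    "Rad21"),
  spermatocytes = c("Jdp2", "Fbxo43", "Dyx1c1", "Piwil1", "Tbpl1",
                    "Prss44"),
  round_spermatids = c("Mpzl3", "Svep1", "Slc4a4", "Wnt7a"),
  elongating_spermatids = c("Prm2", "Dnmt3l"),
  sertoli = c("Dancr", "Sox8", "Sox9"))

#' Illustrative testis marker panel
#'
#' The 22 lineage-specific validation markers for spermatogonia,
#' spermatocytes, round spermatids, elongating spermatids and Sertoli
#' cells, bundled as a named panel. Real panels are user-supplied; this
#' one matches the default gene names of [simulate_dataset()].
#'
#' @return A `MarkerPanel` (without a negative-control set).
#' @export
default_marker_panel <- function() marker_panel(TESTIS_VALIDATION_MARKERS)

#' Simulation configuration
#'
#' Defines a testis-like scRNA-seq simulation: negative-binomial UMI
#' counts with lognormal gene base means and lognormal library-size
#' variation, planted marker genes per cell type, condition effects in the
#' perturbed condition, chromosome-class gene tagging, an optional doublet
#' fraction and an optional coupling between one gene's expression and the
#' number of expressed genes.
#'
#' Defaults: five testis cell types with 200 cells per type and condition,
#' 10 markers per type at log2 fold 3, 2000 genes, negative-binomial size
#' 2, gene base means lognormal(log 0.5, 1) with marker genes drawn from
#' lognormal(log 2.5, 0.3) and planted effect genes given base mean 4 —
#' curated panels select robustly expressed but still type-restricted
#' transcripts, and on the log2(x+1) scale a fold change in a weakly
#' expressed gene is compressed below the callers' thresholds (see the
#' methods vignette) — and hypoxia effects Asxl2 log2 fold -2, Cep162 +2
#' in the spermatid stages, with Asxl2 negatively coupled to the
#' expressed-gene count.
#'
#' @param types cell-type names.
#' @param n_cells_per_condition named list: condition -> named integer
#'   vector of cells per type. Default balanced 200 everywhere for
#'   `"normoxia"` and `"hypoxia"`.
#' @param n_markers_per_type planted markers per type (default 10).
#' @param marker_log2_fold log2 fold elevation of a marker in its own type
#'   (default 3).
#' @param n_genes total genes (default 2000).
#' @param base_expression,marker_base_expression `c(meanlog=, sdlog=)` of
#'   the lognormal gene base means.
#' @param marker_base_max cap on marker base means (default 3 UMIs). A
#'   gene whose baseline already puts it in nearly every cell is not
#'   usable as a marker — curated panels screen such genes out — so the
#'   generator keeps planted markers type-restricted by construction.
#' @param library_size `c(meanlog=, sdlog=)` of the per-cell library
#'   factor (default sdlog 0.3).
#' @param dispersion negative-binomial size parameter (default 2).
#' @param chrom_class_probs probabilities over MT/X/Y/AUTO.
#' @param mt_expression_boost multiplier on MT gene base means (default 5;
#'   mitochondrial transcripts are abundant).
#' @param condition_effects list of `list(gene=, types=, log2_fold=)`
#'   applied in `condition_b`.
#' @param condition_b the perturbed condition (default `"hypoxia"`).
#' @param doublet_rate fraction of emitted cells that are doublets
#'   (default 0.05; must be < 0.2).
#' @param attribute_coupling `list(gene=, strength=)` or `NULL`: the
#'   gene's mean is multiplied by `(mean_library/library)^strength`, so
#'   high expression co-occurs with small libraries and few expressed
#'   genes.
#' @param seed default RNG seed for [simulate_dataset()].
#' @return A list of class `SimulationConfig`.
#' @export
simulation_config <- function(
    types = names(TESTIS_VALIDATION_MARKERS),
    n_cells_per_condition = NULL,
    n_markers_per_type = 10L,
    marker_log2_fold = 3,
    n_genes = 2000L,
    base_expression = c(meanlog = log(0.5), sdlog = 1),
    marker_base_expression = c(meanlog = log(2.5), sdlog = 0.3),
    marker_base_max = 3,
    library_size = c(meanlog = 0, sdlog = 0.3),
    dispersion = 2,
    chrom_class_probs = c(MT = 0.01, X = 0.05, Y = 0.01, AUTO = 0.93),
    mt_expression_boost = 5,
    condition_effects = list(
      list(gene = "Asxl2",
           types = c("round_spermatids", "elongating_spermatids"),
           log2_fold = -2, base_mean = 4),
      list(gene = "Cep162",
           types = c("round_spermatids", "elongating_spermatids"),
           log2_fold = 2, base_mean = 4)),
    condition_b = "hypoxia",
    doublet_rate = 0.05,
    attribute_coupling = list(gene = "Asxl2", strength = 1.5),
    seed = 1L) {
  if (length(types) < 2L) stop("need at least 2 cell types", call. = FALSE)
  if (is.null(n_cells_per_condition)) {
    n_cells_per_condition <- list(
      normoxia = stats::setNames(rep(200L, length(types)), types),
      hypoxia  = stats::setNames(rep(200L, length(types)), types))
  }
  for (cond in names(n_cells_per_condition)) {
    v <- n_cells_per_condition[[cond]]
    if (!all(types %in% names(v)))
      stop("n_cells_per_condition$", cond, " must name every type",
           call. = FALSE)
  }
  if (n_markers_per_type * length(types) > n_genes)
    stop("marker sets exceed the gene count", call. = FALSE)
  if (doublet_rate < 0 || doublet_rate >= 0.2)
    stop("doublet_rate must be in [0, 0.2)", call. = FALSE)
  structure(list(
    types = types, n_cells_per_condition = n_cells_per_condition,
    n_markers_per_type = as.integer(n_markers_per_type),
    marker_log2_fold = marker_log2_fold, n_genes = as.integer(n_genes),
    base_expression = base_expression,
    marker_base_expression = marker_base_expression,
    marker_base_max = marker_base_max,
    library_size = library_size, dispersion = dispersion,
    chrom_class_probs = chrom_class_probs,
    mt_expression_boost = mt_expression_boost,
    condition_effects = condition_effects, condition_b = condition_b,
    doublet_rate = doublet_rate, attribute_coupling = attribute_coupling,
    seed = as.integer(seed)), class = "SimulationConfig")
}

#' Composition preset with a hypoxia-like shift
#'
#' Per-condition cell-type proportions in which the perturbed condition
#' has a lower elongating-spermatid fraction (0.50397 vs 0.42386) and a
#' higher round-spermatid fraction (0.08831 vs 0.11215), the direction and
#' size of the composition shift reported for chronically hypoxic rat
#' testis; the remaining mass is split over the other types in fixed
#' relative proportions.
#'
#' @param n_cells total cells per condition (default 1000).
#' @return Named list suitable for `n_cells_per_condition`.
#' @export
testis_composition <- function(n_cells = 1000L) {
  rest <- c(spermatogonia = 0.10, spermatocytes = 0.23, sertoli = 0.078)
  make <- function(elong, round) {
    p <- c(rest / sum(rest) * (1 - elong - round),
           round_spermatids = round, elongating_spermatids = elong)
    n <- round(n_cells * p)
    stats::setNames(as.integer(n), names(p))
  }
  list(normoxia = make(0.50397, 0.08831),
       hypoxia  = make(0.42386, 0.11215))
}

#' Simulate a testis-like scRNA-seq dataset with ground truth
#'
#' Draws UMI counts from a negative binomial with lognormal gene base
#' means, per-cell lognormal library factors, marker genes elevated
#' `2^marker_log2_fold`-fold in their own type, condition effects applied
#' in the perturbed condition, and optional doublets built as the sum of
#' two same-condition singlet profiles rescaled to 1.4x the mean library
#' size. Fully reproducible from the seed.
#'
#' @param config a [simulation_config()].
#' @param seed overrides `config$seed` when given.
#' @return List with `matrix` (a raw `CountMatrix`), `truth` (list of
#'   per-cell and per-gene data frames), `panel` (the planted
#'   `MarkerPanel`, no negative control) and `config`.
#' @export
simulate_dataset <- function(config = simulation_config(), seed = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  set.seed(seed %||% config$seed)
  types <- config$types
  k <- config$n_markers_per_type
  ng <- config$n_genes

  # gene identities: planted markers first (named after real testis
  # lineage markers where available), then condition-effect genes, then
  # anonymous background genes
  marker_names <- lapply(types, function(t) {
    real <- TESTIS_VALIDATION_MARKERS[[t]] %||% character()
    real <- utils::head(real, k)
    c(real, if (length(real) < k)
      sprintf("%s_m%02d", t, seq_len(k - length(real))))
  })
  names(marker_names) <- types
  effect_genes <- vapply(config$condition_effects, `[[`, "", "gene")
  coupling_gene <- config$attribute_coupling$gene
  special <- unique(c(unlist(marker_names), effect_genes, coupling_gene))
  if (length(special) > ng) stop("n_genes too small", call. = FALSE)
  genes <- c(special, sprintf("gene_%04d", seq_len(ng - length(special))))

  chrom_class <- sample(names(config$chrom_class_probs), ng, replace = TRUE,
                        prob = config$chrom_class_probs)
  base_mu <- stats::rlnorm(ng, config$base_expression["meanlog"],
                           config$base_expression["sdlog"])
  midx <- lapply(marker_names, match, genes)
  for (t in types)
    base_mu[midx[[t]]] <- pmin(
      stats::rlnorm(k, config$marker_base_expression["meanlog"],
                    config$marker_base_expression["sdlog"]),
      config$marker_base_max)
  base_mu[chrom_class == "MT"] <- base_mu[chrom_class == "MT"] *
    config$mt_expression_boost
  for (eff in config$condition_effects)
    if (!is.null(eff$base_mean))
      base_mu[match(eff$gene, genes)] <- eff$base_mean

  # expected gene means per (type, condition)
  group_mu <- function(type, cond) {
    mu <- base_mu
    mu[midx[[type]]] <- mu[midx[[type]]] * 2^config$marker_log2_fold
    if (cond == config$condition_b)
      for (eff in config$condition_effects)
        if (type %in% eff$types) {
          gi <- match(eff$gene, genes)
          mu[gi] <- mu[gi] * 2^eff$log2_fold
        }
    mu
  }

  cells <- list(); truth_rows <- list(); idx <- 0L
  mean_lib <- exp(config$library_size["meanlog"] +
                  config$library_size["sdlog"]^2 / 2)
  cgi <- if (!is.null(coupling_gene)) match(coupling_gene, genes) else NA
  draw_group <- function(n, mu, cond, type_lab) {
    f <- stats::rlnorm(n, config$library_size["meanlog"],
                       config$library_size["sdlog"])
    m <- matrix(stats::rnbinom(n * length(mu),
                               mu = outer(f, mu),
                               size = config$dispersion),
                nrow = n)
    if (!is.na(cgi) && !is.null(config$attribute_coupling)) {
      cf <- (mean_lib / f)^config$attribute_coupling$strength
      m[, cgi] <- stats::rnbinom(n, mu = f * mu[cgi] * cf,
                                 size = config$dispersion)
    }
    m
  }

  counts_blocks <- list()
  for (cond in names(config$n_cells_per_condition)) {
    for (t in types) {
      n <- config$n_cells_per_condition[[cond]][[t]]
      if (n < 1L) next
      mu <- group_mu(t, cond)
      counts_blocks[[length(counts_blocks) + 1L]] <-
        draw_group(n, mu, cond, t)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        true_type = rep(t, n), condition = rep(cond, n),
        is_doublet = FALSE, constituents = rep(t, n),
        stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(rbind, counts_blocks)
  truth_cells <- do.call(rbind, truth_rows)

  # doublets: NB draws around the scaled sum of two same-condition
  # singlet group means
  n_singlet <- nrow(counts)
  n_doub <- round(config$doublet_rate * n_singlet)
  if (n_doub > 0L) {
    doub <- matrix(0L, n_doub, ng)
    drows <- vector("list", n_doub)
    for (d in seq_len(n_doub)) {
      cond <- sample(names(config$n_cells_per_condition), 1L)
      pair <- sample(types, 2L, replace = FALSE)
      mu <- group_mu(pair[1L], cond) + group_mu(pair[2L], cond)
      mu <- mu / sum(mu) * 1.4 * mean_lib * sum(base_mu)
      doub[d, ] <- stats::rnbinom(ng, mu = mu, size = config$dispersion)
      drows[[d]] <- data.frame(
        true_type = "doublet", condition = cond, is_doublet = TRUE,
        constituents = paste(pair, collapse = "+"),
        stringsAsFactors = FALSE)
    }
    counts <- rbind(counts, doub)
    truth_cells <- rbind(truth_cells, do.call(rbind, drows))
  }

  ord <- sample(nrow(counts))
  counts <- counts[ord, , drop = FALSE]
  truth_cells <- truth_cells[ord, , drop = FALSE]
  truth_cells$barcode <- sprintf("cell_%05d", seq_len(nrow(counts)))
  rownames(truth_cells) <- NULL
  truth_cells <- truth_cells[, c("barcode", "true_type", "condition",
                                 "is_doublet", "constituents")]

  marker_of <- rep(NA_character_, ng)
  for (t in types) marker_of[midx[[t]]] <- t
  effect_fold <- rep(0, ng)
  for (eff in config$condition_effects)
    effect_fold[match(eff$gene, genes)] <- eff$log2_fold
  truth_genes <- data.frame(gene_id = genes, chrom_class = chrom_class,
                            marker_of = marker_of,
                            condition_log2_fold = effect_fold,
                            stringsAsFactors = FALSE)

  cm <- count_matrix(counts, truth_cells$barcode, genes, chrom_class,
                     condition = truth_cells$condition)
  list(matrix = cm,
       truth = list(cells = truth_cells, genes = truth_genes),
       panel = marker_panel(marker_names),
       config = config)
}

#' Write a simulated dataset as an MTX bundle with ground truth
#'
#' Emits the exact bundle [read_matrix()] reads (matrix.mtx, barcodes.tsv,
#' features.tsv, annotation.tsv, conditions.tsv) plus `ground_truth.tsv`,
#' `gene_truth.tsv` and the configuration echoed as `sim_config.yaml`.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  write_matrix(sim$matrix, dir)
  utils::write.table(sim$truth$cells, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$genes, file.path(dir, "gene_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, file.path(dir, "sim_config.yaml"))
  invisible(dir)
}

#' Hand-written 6-cell by 12-gene fixture
#'
#' A tiny raw count matrix whose normalization, Gini, chromosome-fraction
#' and enrichment-score values can be verified by hand or by exhaustive
#' enumeration. Cell totals are (10, 20, 10, 10, 10, 10), so the median
#' library is 10 and cell `c2` has scale factor 2: its count of 6 on gene
#' `g01` normalizes to 3 and transforms to log2(4) = 2.
#'
#' @return List with `matrix` (raw `CountMatrix`) and `expected` (list:
#'   `median_total`, `scale_factors`, `norm_c2_g01`, `chrM_pct`).
#' @export
micro_fixture <- function() {
  genes <- sprintf("g%02d", 1:12)
  chrom <- c("MT", "X", "Y", rep("AUTO", 9))
  counts <- rbind(
    c1 = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 0, 0),
    c2 = c(6, 2, 2, 2, 2, 2, 2, 2, 0, 0, 0, 0),
    c3 = c(0, 0, 0, 1, 2, 3, 4, 0, 0, 0, 0, 0),
    c4 = c(0, 0, 0, 0, 0, 0, 0, 0, 10, 0, 0, 0),
    c5 = c(2, 2, 2, 2, 2, 0, 0, 0, 0, 0, 0, 0),
    c6 = c(0, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 0))
  m <- count_matrix(counts, rownames(counts), genes, chrom,
                    condition = rep(c("normoxia", "hypoxia"), each = 3))
  list(matrix = m,
       expected = list(
         median_total = 10,
         scale_factors = c(1, 2, 1, 1, 1, 1),
         norm_c2_g01 = 2,
         chrM_pct = c(10, 30, 0, 0, 20, 0)))
}
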