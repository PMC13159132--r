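#' Pooled two-sample two-sided Student's t-test
#'
#' Classic equal-variance Student's t (not Welch), two-sided. Zero pooled
#' variance is handled by sentinel rather than error: equal means give
#' statistic 0 and p = 1, unequal means give an infinite statistic and
#' p = 0, so constant genes behave sensibly inside genome-wide scans.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return List with `statistic` and `p_value`.
#' @export
two_sided_t <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  res <- pooled_t_stat(matrix(group_a, ncol = 1L),
                       matrix(group_b, ncol = 1L))
  list(statistic = res$statistic[1L], p_value = res$p_value[1L])
}

# Vectorized pooled t over the columns of two matrices (cells x genes).
pooled_t_stat <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- colSums((a - rep(ma, each = na))^2) / (na - 1)
  vb <- colSums((b - rep(mb, each = nb))^2) / (nb - 1)
  df <- na + nb - 2
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  stat <- (ma - mb) / se
  p <- 2 * stats::pt(-abs(stat), df)
  zero <- se == 0
  if (any(zero)) {
    eq <- zero & (ma == mb)
    stat[eq] <- 0; p[eq] <- 1
    ne <- zero & (ma != mb)
    stat[ne] <- sign(ma[ne] - mb[ne]) * Inf
    p[ne] <- 0
  }
  list(statistic = stat, p_value = p)
}

#' Call cell-type-specific genes
#'
#' Compares one cell type against all other cells, gene by gene, and flags
#' a gene as type-specific when it meets all five criteria, evaluated
#' independently so each flag is reported:
#' 1. detected (count > 0) in at least `min_pct_in` of the type's cells;
#' 2. detection rate in the type exceeds the rate elsewhere by at least
#'    `min_pct_diff` (set `detection_rule = "overall"` for the alternative
#'    reading: detected in at least `min_pct_diff` of all cells);
#' 3. pooled two-sided Student's t p-value below `max_p`;
#' 4. log2 fold change of at least `min_log2fc`, computed as the
#'    difference of group means of the already log2-scaled values;
#' 5. the gene's overall mean expression exceeds the median of all genes'
#'    overall means.
#'
#' @param nm a `NormalizedMatrix`.
#' @param labels per-cell type labels.
#' @param target_type the type to contrast against the rest.
#' @param min_pct_in default 0.20.
#' @param min_pct_diff default 0.10.
#' @param max_p default 1e-10.
#' @param min_log2fc default 2.
#' @param detection_rule `"difference"` (default) or `"overall"`, the two
#'   readings of criterion 2.
#' @return Data frame, one row per gene: `gene_id`, `p_value`, `log2fc`,
#'   `pct_in`, `pct_out`, `mean_overall`, `crit1`..`crit5`, `passes`.
#' @export
specific_genes <- function(nm, labels, target_type, min_pct_in = 0.20,
                           min_pct_diff = 0.10, max_p = 1e-10,
                           min_log2fc = 2,
                           detection_rule = c("difference", "overall")) {
  stopifnot(is(nm, "NormalizedMatrix"), length(labels) == nrow(nm$values))
  detection_rule <- match.arg(detection_rule)
  in_idx <- which(labels == target_type)
  out_idx <- which(labels != target_type)
  if (!length(in_idx))
    stop("unknown cell type '", target_type, "'", call. = FALSE)
  if (length(in_idx) < 2L || length(out_idx) < 2L)
    stop("need at least 2 cells on each side of the contrast",
         call. = FALSE)
  v_in <- nm$values[in_idx, , drop = FALSE]
  v_out <- nm$values[out_idx, , drop = FALSE]
  pct_in <- colMeans(v_in > 0)
  pct_out <- colMeans(v_out > 0)
  tt <- pooled_t_stat(v_in, v_out)
  log2fc <- colMeans(v_in) - colMeans(v_out)
  mean_overall <- colMeans(nm$values)
  crit1 <- pct_in >= min_pct_in
  crit2 <- if (detection_rule == "difference")
    (pct_in - pct_out) >= min_pct_diff
  else colMeans(nm$values > 0) >= min_pct_diff
  crit3 <- tt$p_value < max_p
  crit4 <- log2fc >= min_log2fc
  crit5 <- mean_overall > median(mean_overall)
  data.frame(gene_id = nm$genes, p_value = tt$p_value, log2fc = log2fc,
             pct_in = pct_in, pct_out = pct_out,
             mean_overall = mean_overall,
             crit1 = crit1, crit2 = crit2, crit3 = crit3, crit4 = crit4,
             crit5 = crit5,
             passes = crit1 & crit2 & crit3 & crit4 & crit5,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call differentially expressed genes between two conditions
#'
#' Within one cell type, contrasts the cells of `condition_b` against
#' those of `condition_a`, gene by gene. A gene passes when it meets all
#' three criteria: pooled two-sided Student's t p-value below `max_p`,
#' absolute log2 fold change of at least `min_abs_log2fc`, and overall
#' mean expression above the median of all genes' overall means. The
#' reported `log2fc` and `direction` describe condition_b relative to
#' condition_a (`"up"` = higher in condition_b).
#'
#' @param nm a `NormalizedMatrix`.
#' @param labels per-cell type labels.
#' @param cell_type restrict the contrast to this type's cells.
#' @param condition_a,condition_b condition labels (taken from
#'   `nm$condition`).
#' @param max_p default 1e-10.
#' @param min_abs_log2fc default 1.
#' @return Data frame per gene: `gene_id`, `p_value`, `log2fc`, `pct_a`,
#'   `pct_b`, `mean_overall`, `crit1`..`crit3`, `passes`, `direction`.
#' @export
condition_degs <- function(nm, labels, cell_type, condition_a, condition_b,
                           max_p = 1e-10, min_abs_log2fc = 1) {
  stopifnot(is(nm, "NormalizedMatrix"), length(labels) == nrow(nm$values))
  type_idx <- which(labels == cell_type)
  if (!length(type_idx))
    stop("unknown cell type '", cell_type, "'", call. = FALSE)
  cond <- nm$condition[type_idx]
  a_idx <- type_idx[cond == condition_a]
  b_idx <- type_idx[cond == condition_b]
  if (length(a_idx) < 2L)
    stop("condition '", condition_a, "' has fewer than 2 cells of type '",
         cell_type, "'", call. = FALSE)
  if (length(b_idx) < 2L)
    stop("condition '", condition_b, "' has fewer than 2 cells of type '",
         cell_type, "'", call. = FALSE)
  v_a <- nm$values[a_idx, , drop = FALSE]
  v_b <- nm$values[b_idx, , drop = FALSE]
  tt <- pooled_t_stat(v_b, v_a)
  log2fc <- colMeans(v_b) - colMeans(v_a)
  mean_overall <- colMeans(nm$values)
  crit1 <- tt$p_value < max_p
  crit2 <- abs(log2fc) >= min_abs_log2fc
  crit3 <- mean_overall > median(mean_overall)
  data.frame(gene_id = nm$genes, p_value = tt$p_value, log2fc = log2fc,
             pct_a = colMeans(v_a > 0), pct_b = colMeans(v_b > 0),
             mean_overall = mean_overall,
             crit1 = crit1, crit2 = crit2, crit3 = crit3,
             passes = crit1 & crit2 & crit3,
             direction = ifelse(log2fc > 0, "up",
                                ifelse(log2fc < 0, "down", "none")),
             stringsAsFactors = FALSE, row.names = NULL)
}
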