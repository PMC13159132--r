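#' Gini index of expression inequality
#'
#' Inequality of a cell's expression over its expressed genes, computed
#' with the order-statistic estimator
#' \deqn{G = \frac{1}{n}\left(n + 1 - 2\,\frac{\sum_{i=1}^{n}(n+1-i)\,y_i}
#'   {\sum_{i=1}^{n} y_i}\right)}
#' where the \eqn{y_i} are the values sorted ascending. 0 means perfectly
#' even expression; the maximum for `n` values is `(n - 1)/n` (all
#' expression in one value). Algebraically identical to half the relative
#' mean absolute difference. No small-sample correction is applied.
#'
#' The index is computed over the values supplied: to measure inequality
#' among a cell's expressed genes (as [cell_attributes()] does), pass only
#' the positive values. Zeros are legal inputs and count as values with no
#' mass, raising the index.
#'
#' @param expr non-negative numeric vector (`NA`s dropped) with positive
#'   sum.
#' @return The Gini index in \[0, (n-1)/n\], or `NA_real_` for an empty or
#'   all-zero vector.
#' @export
gini_index <- function(expr) {
  y <- expr[!is.na(expr)]
  if (any(y < 0)) stop("gini_index requires non-negative values",
                       call. = FALSE)
  n <- length(y)
  if (n == 0L || sum(y) == 0) return(NA_real_)
  y <- sort(y)
  (n + 1 - 2 * sum((n + 1 - seq_len(n)) * y) / sum(y)) / n
}

#' Chromosome-class UMI fractions per cell
#'
#' Percentage of each cell's UMIs on mitochondrial (chrM%), X (chrX%) and
#' Y (chrY%) genes, computed on raw counts. A high chrM% marks a stressed
#' or dying cell; chrX%/chrY% track sex-chromosome activity, which in
#' spermatogenesis drops sharply at meiotic sex-chromosome inactivation.
#'
#' @param m raw-layer `CountMatrix`.
#' @return Data frame with `chrM_pct`, `chrX_pct`, `chrY_pct` per cell
#'   (each in \[0, 100\]; `NA` for a zero-total cell).
#' @export
chrom_fractions <- function(m) {
  stopifnot(is(m, "CountMatrix"))
  totals <- Matrix::rowSums(m$counts)
  pct <- function(cls) {
    idx <- m$chrom_class == cls
    if (!any(idx)) return(rep(0, length(totals)))
    unname(100 * Matrix::rowSums(m$counts[, idx, drop = FALSE]) / totals)
  }
  out <- data.frame(chrM_pct = pct("MT"), chrX_pct = pct("X"),
                    chrY_pct = pct("Y"))
  out[totals == 0, ] <- NA_real_
  out
}

#' Within-type expression diversity
#'
#' Dissimilarity of each cell from the other cells of its type: one minus
#' the mean Pearson correlation between the cell's normalized expression
#' profile and every other same-type cell. 0 means the type is perfectly
#' homogeneous; values near 1 indicate uncorrelated profiles. Pairs
#' involving a zero-variance profile have no defined correlation and are
#' excluded from the mean (with a message); a singleton type yields `NA`.
#'
#' @param values cells x genes numeric matrix (normalized expression) for
#'   the cells of one type.
#' @return Numeric vector of per-cell diversity values in \[0, 2\].
#' @export
expression_diversity <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (n < 2L) return(rep(NA_real_, n))
  sds <- apply(values, 1L, stats::sd)
  if (any(sds == 0))
    message(sum(sds == 0), " zero-variance cell(s): their pairwise ",
            "correlations are excluded from the diversity means")
  cm <- suppressWarnings(stats::cor(t(values)))
  diag(cm) <- NA
  1 - rowMeans(cm, na.rm = TRUE)
}

#' Per-cell attribute table
#'
#' Computes the standard per-cell attributes in one pass: the Gini index of
#' normalized expression over expressed genes, chromosome-class UMI
#' percentages on raw counts, log10 total UMIs, the number of detected
#' genes and, when labels are supplied, the within-type diversity.
#'
#' @param m raw-layer `CountMatrix` (source of UMI totals and chromosome
#'   fractions).
#' @param nm matching `NormalizedMatrix` (source of Gini and diversity).
#' @param labels optional per-cell type labels for diversity; cells of
#'   singleton types (or without labels) get `NA` diversity.
#' @return Data frame, one row per cell: `barcode`, `gini`, `chrM_pct`,
#'   `chrX_pct`, `chrY_pct`, `umi_log10`, `n_genes`, `diversity`.
#' @export
cell_attributes <- function(m, nm, labels = NULL) {
  stopifnot(is(m, "CountMatrix"), is(nm, "NormalizedMatrix"),
            identical(m$barcodes, nm$barcodes))
  totals <- Matrix::rowSums(m$counts)
  out <- data.frame(
    barcode = m$barcodes,
    gini = apply(nm$values, 1L, function(v) gini_index(v[v > 0])),
    chrom_fractions(m),
    umi_log10 = log10(totals),
    n_genes = as.integer(Matrix::rowSums(m$counts > 0)),
    diversity = NA_real_,
    stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(out))
    for (t in unique(labels)) {
      idx <- which(labels == t)
      if (length(idx) >= 2L)
        out$diversity[idx] <-
          expression_diversity(nm$values[idx, , drop = FALSE])
    }
  }
  out
}

#' Correlate a gene's expression with a per-cell attribute
#'
#' Pearson correlation between one gene's normalized expression and a cell
#' attribute, restricted to the cells that express the gene (expression
#' > 0), per cell-type stratum and pooled. This is the analysis behind
#' questions like "does high expression of a repressor go with fewer
#' expressed genes?": a negative coefficient in expressing cells supports
#' a repressive role.
#'
#' @param nm a `NormalizedMatrix`.
#' @param gene_id gene to correlate.
#' @param attributes data frame from [cell_attributes()].
#' @param attribute one of `"gini"`, `"n_genes"`, `"umi_log10"` (or any
#'   numeric column of `attributes`).
#' @param labels optional per-cell type labels defining strata.
#' @param min_cells smallest stratum evaluated (default 3); smaller strata
#'   are skipped with a warning.
#' @return Data frame: `gene_id`, `attribute`, `stratum` (cell type or
#'   `"pooled"`), `pcc`, `n_cells`. A constant attribute or constant
#'   expression yields `NA` (undefined), never a silent 0.
#' @export
attribute_gene_correlation <- function(nm, gene_id, attributes,
                                       attribute = "gini", labels = NULL,
                                       min_cells = 3L) {
  stopifnot(is(nm, "NormalizedMatrix"), attribute %in% names(attributes))
  gi <- match(gene_id, nm$genes)
  if (is.na(gi)) stop("gene '", gene_id, "' not in matrix", call. = FALSE)
  expr <- nm$values[, gi]
  attr_vals <- attributes[[attribute]]
  strata <- if (is.null(labels)) list() else split(seq_along(expr), labels)
  strata[["pooled"]] <- seq_along(expr)
  rows <- lapply(names(strata), function(s) {
    idx <- strata[[s]]
    idx <- idx[expr[idx] > 0 & !is.na(attr_vals[idx])]
    if (length(idx) < min_cells) {
      warning("stratum '", s, "': fewer than ", min_cells,
              " expressing cells, skipped", call. = FALSE)
      return(NULL)
    }
    r <- if (stats::sd(expr[idx]) == 0 || stats::sd(attr_vals[idx]) == 0)
      NA_real_
    else stats::cor(expr[idx], attr_vals[idx])
    data.frame(gene_id = gene_id, attribute = attribute, stratum = s,
               pcc = r, n_cells = length(idx), stringsAsFactors = FALSE)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
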