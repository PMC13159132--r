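#' @useDynLib permtyper, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods as is
#' @importFrom stats median
NULL

CHROM_CLASSES <- c("MT", "X", "Y", "AUTO")

#' Construct a cells-by-genes UMI count matrix with metadata
#'
#' Container for a raw droplet scRNA-seq count matrix together with the
#' per-gene and per-cell metadata every downstream stage needs: barcodes,
#' gene identifiers, a chromosome class per gene (`MT`, `X`, `Y` or `AUTO`)
#' and an optional experimental condition per cell.
#'
#' @param counts cells x genes matrix of non-negative integer UMI counts
#'   (dense or sparse; stored as `dgCMatrix`).
#' @param barcodes character vector of unique cell identifiers (rows).
#' @param genes character vector of unique gene identifiers (columns).
#' @param chrom_class character vector, one of `"MT"`, `"X"`, `"Y"`,
#'   `"AUTO"` per gene.
#' @param condition optional character vector of per-cell condition labels
#'   (e.g. `"normoxia"` / `"hypoxia"`); defaults to `NA`.
#' @param symbols optional gene symbols (kept for display; joins always use
#'   `genes`).
#' @return An object of class `CountMatrix`.
#' @export
count_matrix <- function(counts, barcodes, genes, chrom_class,
                         condition = NULL, symbols = NULL) {
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  if (nrow(counts) != length(barcodes))
    stop("count_matrix: ", nrow(counts), " rows but ", length(barcodes),
         " barcodes", call. = FALSE)
  if (ncol(counts) != length(genes))
    stop("count_matrix: ", ncol(counts), " columns but ", length(genes),
         " genes", call. = FALSE)
  if (anyDuplicated(barcodes))
    stop("count_matrix: duplicate barcodes: ",
         paste(unique(barcodes[duplicated(barcodes)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(genes))
    stop("count_matrix: duplicate gene ids: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  if (length(chrom_class) != length(genes))
    stop("count_matrix: chrom_class must have one entry per gene",
         call. = FALSE)
  bad <- !chrom_class %in% CHROM_CLASSES
  if (any(bad))
    stop("count_matrix: invalid chromosome class for gene(s): ",
         paste(genes[bad], collapse = ", "), call. = FALSE)
  x <- counts@x
  if (any(!is.finite(x)) || any(x < 0))
    stop("count_matrix: counts must be finite and non-negative",
         call. = FALSE)
  if (any(x != round(x)))
    stop("count_matrix: raw counts must be integers (UMI units)",
         call. = FALSE)
  if (is.null(condition)) condition <- rep(NA_character_, length(barcodes))
  if (length(condition) != length(barcodes))
    stop("count_matrix: condition must have one entry per cell",
         call. = FALSE)
  dimnames(counts) <- list(barcodes, genes)
  structure(list(
    counts      = counts,
    barcodes    = as.character(barcodes),
    genes       = as.character(genes),
    chrom_class = as.character(chrom_class),
    condition   = as.character(condition),
    symbols     = if (is.null(symbols)) as.character(genes)
                  else as.character(symbols),
    layer       = "raw"
  ), class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat("CountMatrix: ", length(x$barcodes), " cells x ", length(x$genes),
      " genes (", x$layer, " layer)\n", sep = "")
  cat("  chromosome classes:",
      paste(sprintf("%s=%d", CHROM_CLASSES,
                    tabulate(factor(x$chrom_class, CHROM_CLASSES), 4L)),
            collapse = " "), "\n")
  cond <- x$condition[!is.na(x$condition)]
  if (length(cond))
    cat("  conditions:", paste(names(table(cond)), table(cond),
                               sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Read a 10x-style MatrixMarket count bundle
#'
#' Reads a MatrixMarket coordinate matrix plus its `barcodes.tsv` and
#' `features.tsv` sidecars and a gene-annotation table assigning each gene a
#' chromosome class, and returns a cells-by-genes [count_matrix()]. 10x
#' writes genes as matrix rows, so the on-disk orientation defaults to
#' `genes_x_cells` and is transposed on read; set
#' `orientation = "cells_x_genes"` for matrices already in analysis
#' orientation.
#'
#' @param mtx_path path to the `.mtx` file (optionally gzipped).
#' @param barcodes_path one-column TSV of cell barcodes.
#' @param features_path TSV with 1-3 columns: gene id, optional symbol,
#'   optional feature type. Joins use column 1.
#' @param annot_path TSV with columns `gene_id` and `chrom_class`
#'   (values `MT`/`X`/`Y`/`AUTO`); a header row is detected automatically.
#' @param orientation on-disk orientation of the matrix.
#' @param condition optional: a per-cell character vector, or a path to a
#'   TSV with columns barcode and condition.
#' @return A `CountMatrix`.
#' @export
read_matrix <- function(mtx_path, barcodes_path, features_path, annot_path,
                        orientation = c("genes_x_cells", "cells_x_genes"),
                        condition = NULL) {
  orientation <- match.arg(orientation)
  m <- Matrix::readMM(mtx_path)
  if (orientation == "genes_x_cells") m <- Matrix::t(m)
  barcodes <- read_column_tsv(barcodes_path)[[1L]]
  feats <- read_column_tsv(features_path)
  genes <- feats[[1L]]
  symbols <- if (ncol(feats) >= 2L) feats[[2L]] else genes
  if (nrow(m) != length(barcodes))
    stop("read_matrix: matrix has ", nrow(m), " cells but barcodes file has ",
         length(barcodes), " rows", call. = FALSE)
  if (ncol(m) != length(genes))
    stop("read_matrix: matrix has ", ncol(m), " genes but features file has ",
         length(genes), " rows", call. = FALSE)
  annot <- read_annotation(annot_path)
  cls <- annot$chrom_class[match(genes, annot$gene_id)]
  if (anyNA(cls))
    stop("read_matrix: no chromosome class for gene(s): ",
         paste(genes[is.na(cls)], collapse = ", "), call. = FALSE)
  if (!is.null(condition) && length(condition) == 1L &&
      file.exists(condition)) {
    ctab <- read_column_tsv(condition)
    condition <- ctab[[2L]][match(barcodes, ctab[[1L]])]
  }
  count_matrix(m, barcodes, genes, cls, condition = condition,
               symbols = symbols)
}

# Headerless TSV reader that tolerates an optional header line.
read_column_tsv <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#",
                          colClasses = "character")
  df
}

read_annotation <- function(path) {
  df <- read_column_tsv(path)
  if (ncol(df) < 2L)
    stop("gene annotation must have two columns: gene_id, chrom_class",
         call. = FALSE)
  # drop a header row if present
  if (tolower(df[[2L]][1L]) %in% c("chrom_class", "class")) df <- df[-1L, ]
  data.frame(gene_id = df[[1L]], chrom_class = df[[2L]],
             stringsAsFactors = FALSE)
}

#' Write a CountMatrix as a 10x-style MTX bundle
#'
#' Inverse of [read_matrix()]: emits `matrix.mtx`, `barcodes.tsv`,
#' `features.tsv`, `annotation.tsv` and, when condition labels are present,
#' `conditions.tsv` under `dir`. The matrix is written genes-by-cells to
#' match the 10x on-disk convention.
#'
#' @param m a `CountMatrix`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_matrix <- function(m, dir) {
  stopifnot(is(m, "CountMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mm <- Matrix::t(m$counts)
  dimnames(mm) <- NULL
  Matrix::writeMM(mm, file.path(dir, "matrix.mtx"))
  writeLines(m$barcodes, file.path(dir, "barcodes.tsv"))
  utils::write.table(
    data.frame(m$genes, m$symbols, "Gene Expression"),
    file.path(dir, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(m$genes, m$chrom_class),
    file.path(dir, "annotation.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!all(is.na(m$condition)))
    utils::write.table(
      data.frame(m$barcodes, m$condition),
      file.path(dir, "conditions.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Filter cells and genes by detection thresholds
#'
#' Retains cells in which at least `min_genes_per_cell` genes are detected
#' (count > 0) and genes detected in strictly more than `min_cells_per_gene`
#' cells. The cell filter is applied first, on the input matrix; the gene
#' filter is then applied once on the cell-filtered matrix, with no
#' iteration, so the result is deterministic and reported in one pass.
#'
#' @param m raw-layer `CountMatrix`.
#' @param min_genes_per_cell keep cells with at least this many detected
#'   genes (default 500).
#' @param min_cells_per_gene keep genes detected in more than this many
#'   cells (default 10; note the strict inequality).
#' @return The filtered `CountMatrix`, with a `filter_report` attribute
#'   (list: `cells_in`, `cells_removed`, `genes_in`, `genes_removed`,
#'   thresholds).
#' @export
filter_cells_genes <- function(m, min_genes_per_cell = 500,
                               min_cells_per_gene = 10) {
  stopifnot(is(m, "CountMatrix"))
  if (m$layer != "raw")
    stop("filter_cells_genes expects a raw-layer matrix", call. = FALSE)
  detected <- m$counts > 0
  keep_cells <- Matrix::rowSums(detected) >= min_genes_per_cell
  if (!any(keep_cells))
    stop("empty after filtering: no cell reaches ", min_genes_per_cell,
         " detected genes", call. = FALSE)
  keep_genes <- Matrix::colSums(detected[keep_cells, , drop = FALSE]) >
    min_cells_per_gene
  if (!any(keep_genes))
    stop("empty after filtering: no gene is detected in more than ",
         min_cells_per_gene, " retained cells", call. = FALSE)
  out <- count_matrix(m$counts[keep_cells, keep_genes, drop = FALSE],
                      m$barcodes[keep_cells], m$genes[keep_genes],
                      m$chrom_class[keep_genes],
                      condition = m$condition[keep_cells],
                      symbols = m$symbols[keep_genes])
  attr(out, "filter_report") <- list(
    cells_in = length(m$barcodes),
    cells_removed = sum(!keep_cells),
    genes_in = length(m$genes),
    genes_removed = sum(!keep_genes),
    min_genes_per_cell = min_genes_per_cell,
    min_cells_per_gene = min_cells_per_gene)
  out
}

#' Median-ratio normalization with log2 transform
#'
#' Divides each cell's counts by a per-cell scale factor equal to the ratio
#' of that cell's total UMIs to the median total over cells (the standard
#' midpoint median), so that after scaling every cell's total equals the
#' median raw total, and then transforms entrywise with `log2(x + 1)`.
#'
#' @param m filtered raw-layer `CountMatrix`; every cell total must be
#'   positive.
#' @return A `NormalizedMatrix`: list with `values` (cells x genes dense
#'   log2 normalized expression), `scale_factors`, `median_total` and the
#'   metadata carried over from `m`.
#' @export
normalize_counts <- function(m) {
  stopifnot(is(m, "CountMatrix"))
  if (m$layer != "raw")
    stop("normalize_counts expects a raw-layer matrix", call. = FALSE)
  totals <- Matrix::rowSums(m$counts)
  if (any(totals <= 0))
    stop("zero-total cell(s) present: run filter_cells_genes() first",
         call. = FALSE)
  median_total <- median(totals)
  scale_factors <- totals / median_total
  values <- as.matrix(m$counts / scale_factors)
  values <- log2(values + 1)
  dimnames(values) <- list(m$barcodes, m$genes)
  structure(list(
    values        = values,
    scale_factors = scale_factors,
    median_total  = median_total,
    barcodes      = m$barcodes,
    genes         = m$genes,
    chrom_class   = m$chrom_class,
    condition     = m$condition,
    symbols       = m$symbols,
    layer         = "normalized"
  ), class = "NormalizedMatrix")
}

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat("NormalizedMatrix: ", length(x$barcodes), " cells x ",
      length(x$genes), " genes; median library ", x$median_total,
      " UMIs\n", sep = "")
  invisible(x)
}

#' @export
dim.NormalizedMatrix <- function(x) dim(x$values)
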