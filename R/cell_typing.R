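#' Marker panel constructor
#'
#' A marker panel maps cell-type names to marker gene identifiers and
#' optionally carries a negative-control gene set, disjoint from every
#' marker list, used to compute each cell's control enrichment score. When
#' no control set is supplied, [assign_cell_types()] draws one (default 500
#' genes not overlapping any marker list) once per run and shares it across
#' all cells so control scores are comparable.
#'
#' @param markers named list; each element a character vector of gene ids
#'   for one cell type. Order defines the tie-break order for equal
#'   enrichment scores.
#' @param negative_control optional character vector of gene ids disjoint
#'   from all marker lists.
#' @return An object of class `MarkerPanel`.
#' @export
marker_panel <- function(markers, negative_control = NULL) {
  if (!is.list(markers) || is.null(names(markers)) ||
      any(!nzchar(names(markers))))
    stop("markers must be a named list of gene-id vectors", call. = FALSE)
  if (any(lengths(markers) < 1L))
    stop("every cell type needs at least one marker gene", call. = FALSE)
  all_markers <- unique(unlist(markers, use.names = FALSE))
  if (!is.null(negative_control)) {
    clash <- intersect(negative_control, all_markers)
    if (length(clash))
      stop("negative-control genes overlap marker lists: ",
           paste(utils::head(clash, 5L), collapse = ", "), call. = FALSE)
  }
  structure(list(
    types = names(markers),
    markers = lapply(markers, as.character),
    negative_control = as.character(negative_control %||% character())
  ), class = "MarkerPanel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.MarkerPanel <- function(x, ...) {
  cat("MarkerPanel:", length(x$types), "cell types\n")
  for (t in x$types)
    cat(sprintf("  %-22s %d markers\n", t, length(x$markers[[t]])))
  cat("  negative control:", length(x$negative_control), "genes\n")
  invisible(x)
}

#' Read a marker panel from TSV or JSON
#'
#' TSV panels have two columns (cell type, gene id), one marker per row,
#' optional header. JSON panels are an object mapping type names to arrays
#' of gene ids, with an optional `negative_control` array.
#'
#' @param path panel file; format chosen by extension (`.json` vs TSV).
#' @return A `MarkerPanel`.
#' @export
read_marker_panel <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    nc <- obj[["negative_control"]]
    obj[["negative_control"]] <- NULL
    return(marker_panel(obj, negative_control = nc))
  }
  df <- read_column_tsv(path)
  if (ncol(df) < 2L)
    stop("marker panel TSV needs two columns: type, gene_id", call. = FALSE)
  if (tolower(df[[1L]][1L]) %in% c("type", "cell_type")) df <- df[-1L, ]
  marker_panel(split(df[[2L]], factor(df[[1L]], unique(df[[1L]]))))
}

#' Typing thresholds
#'
#' The three assignment criteria: a type is a candidate for a cell when
#' more than `min_marker_fraction` of its markers are detected, the
#' empirical FDR is below `max_fdr` and the enrichment score is at least
#' `min_es`. With `n_perm` permutations the FDR is granular in steps of
#' `1/n_perm`, so at the defaults (`n_perm = 1000`, `max_fdr = 0.001`)
#' FDR < 0.001 holds exactly when no permutation exceeds the observed mean.
#'
#' @param min_marker_fraction detected-marker fraction that must be
#'   exceeded (default 0.20).
#' @param max_fdr empirical FDR bound, strict (default 0.001).
#' @param min_es minimum enrichment score, inclusive (default 5).
#' @param n_perm number of permutations (default 1000).
#' @return A list of class `TypingThresholds`.
#' @export
typing_thresholds <- function(min_marker_fraction = 0.20, max_fdr = 0.001,
                              min_es = 5, n_perm = 1000L) {
  stopifnot(min_marker_fraction > 0, min_marker_fraction < 1,
            max_fdr > 0, max_fdr <= 1, min_es > 0, n_perm >= 1)
  structure(list(min_marker_fraction = min_marker_fraction,
                 max_fdr = max_fdr, min_es = min_es,
                 n_perm = as.integer(n_perm)),
            class = "TypingThresholds")
}

#' Fraction of marker genes detected in a cell
#'
#' @param cell_expr numeric expression vector for one cell (named by gene
#'   id when `markers` is a character vector).
#' @param markers marker genes, as indices into `cell_expr` or gene ids.
#' @return Fraction of markers with expression > 0, in \[0, 1\].
#' @export
marker_fraction <- function(cell_expr, markers) {
  idx <- resolve_genes(cell_expr, markers)
  if (!length(idx)) stop("empty marker set", call. = FALSE)
  mean(cell_expr[idx] > 0)
}

resolve_genes <- function(cell_expr, markers) {
  if (is.character(markers)) {
    idx <- match(markers, names(cell_expr))
    idx[!is.na(idx)]
  } else as.integer(markers)
}

#' Permutation background of marker-mean expression
#'
#' For one cell, draws `n_perm` gene sets of size `k` uniformly without
#' replacement from the cell's full expression vector and returns the mean
#' expression of each set. This is the expected random background against
#' which an observed marker mean is scored; it preserves the cell's own
#' expression-value distribution. Uses R's RNG stream: call `set.seed()`
#' (or pass `seed` to the run-level wrappers) for reproducibility.
#'
#' @param cell_expr numeric expression vector for one cell.
#' @param k marker-set size to emulate.
#' @param n_perm number of permutations (default 1000).
#' @return Numeric vector of `n_perm` background means.
#' @export
permutation_background <- function(cell_expr, k, n_perm = 1000L) {
  perm_background_means(as.numeric(cell_expr), as.integer(k),
                        as.integer(n_perm))
}

#' Enrichment score
#'
#' Ratio of the observed marker-mean expression to the mean of the
#' permutation background. Degenerate backgrounds are handled by sentinel:
#' a zero background mean with positive observed mean yields `Inf`
#' (criteria-passing), and zero observed with zero background yields 0, so
#' cells with no expression at all are never typed.
#'
#' @param observed_mean mean expression of the marker genes in the cell.
#' @param background numeric vector from [permutation_background()].
#' @return The enrichment score (non-negative, possibly `Inf`).
#' @export
enrichment_score <- function(observed_mean, background) {
  if (!length(background)) stop("empty background", call. = FALSE)
  bg <- mean(background)
  if (bg == 0) {
    if (observed_mean > 0) return(Inf)
    return(0)
  }
  observed_mean / bg
}

#' Empirical false discovery rate
#'
#' Fraction of permutation background means strictly greater than the
#' observed marker mean. Always a multiple of `1/length(background)`.
#'
#' @inheritParams enrichment_score
#' @return FDR in \[0, 1\].
#' @export
empirical_fdr <- function(observed_mean, background) {
  if (!length(background)) stop("empty background", call. = FALSE)
  mean(background > observed_mean)
}

# Score one cell against resolved marker index sets.
score_cell <- function(cell_expr, marker_idx, control_idx, thresholds) {
  n_types <- length(marker_idx)
  es <- fdr <- frac <- obs <- numeric(n_types)
  for (i in seq_len(n_types)) {
    idx <- marker_idx[[i]]
    obs[i] <- mean(cell_expr[idx])
    frac[i] <- mean(cell_expr[idx] > 0)
    bg <- perm_background_means(cell_expr, length(idx), thresholds$n_perm)
    es[i] <- enrichment_score(obs[i], bg)
    fdr[i] <- empirical_fdr(obs[i], bg)
  }
  cobs <- mean(cell_expr[control_idx])
  cbg <- perm_background_means(cell_expr, length(control_idx),
                               thresholds$n_perm)
  list(es = es, fdr = fdr, frac = frac, obs = obs,
       control_es = enrichment_score(cobs, cbg))
}

label_from_scores <- function(sc, types, thresholds) {
  cand <- sc$frac > thresholds$min_marker_fraction &
    sc$fdr < thresholds$max_fdr & sc$es >= thresholds$min_es
  if (!any(cand)) return("no_type_match")
  ic <- which(cand)
  best <- ic[which.max(sc$es[ic])]  # higher ES wins; ties by panel order
  if (sc$es[best] < sc$control_es) return("random_others")
  types[best]
}

#' Assign a putative cell type to one cell
#'
#' Computes, for each panel type, the detected-marker fraction, the
#' permutation enrichment score and the empirical FDR, plus the enrichment
#' score of the negative-control gene set. Candidate types must satisfy all
#' three criteria (see [typing_thresholds()]); among candidates the type
#' with the higher enrichment score is assigned, unless its score falls
#' below the control score, in which case the cell is labelled
#' `random_others`. With no candidates the label is `no_type_match`.
#'
#' @param cell_expr named numeric vector of normalized (log2) expression
#'   for one cell.
#' @param panel a `MarkerPanel` whose `negative_control` is non-empty.
#' @param thresholds a [typing_thresholds()] object.
#' @return One-row data frame: `label`, `control_es`, and per-type columns
#'   `es_*`, `fdr_*`, `frac_*`, `mean_*`.
#' @export
assign_cell_type <- function(cell_expr, panel,
                             thresholds = typing_thresholds()) {
  stopifnot(is(panel, "MarkerPanel"))
  rp <- resolve_panel(panel, names(cell_expr))
  sc <- score_cell(as.numeric(cell_expr), rp$marker_idx, rp$control_idx,
                   thresholds)
  row <- data.frame(label = label_from_scores(sc, panel$types, thresholds),
                    control_es = sc$control_es, stringsAsFactors = FALSE)
  for (i in seq_along(panel$types)) {
    t <- panel$types[i]
    row[[paste0("es_", t)]] <- sc$es[i]
    row[[paste0("fdr_", t)]] <- sc$fdr[i]
    row[[paste0("frac_", t)]] <- sc$frac[i]
    row[[paste0("mean_", t)]] <- sc$obs[i]
  }
  row
}

resolve_panel <- function(panel, gene_ids) {
  marker_idx <- vector("list", length(panel$types))
  names(marker_idx) <- panel$types
  for (t in panel$types) {
    idx <- match(panel$markers[[t]], gene_ids)
    if (anyNA(idx)) {
      missing <- panel$markers[[t]][is.na(idx)]
      warning("dropping ", length(missing), " unresolvable marker(s) for ",
              t, ": ", paste(utils::head(missing, 5L), collapse = ", "),
              call. = FALSE)
      idx <- idx[!is.na(idx)]
    }
    if (!length(idx))
      stop("no marker genes of type '", t, "' resolve against the matrix",
           call. = FALSE)
    marker_idx[[t]] <- idx
  }
  if (!length(panel$negative_control))
    stop("panel has no negative-control gene set; draw one with ",
         "draw_negative_control() or use assign_cell_types()", call. = FALSE)
  control_idx <- match(panel$negative_control, gene_ids)
  control_idx <- control_idx[!is.na(control_idx)]
  if (!length(control_idx))
    stop("no negative-control genes resolve against the matrix",
         call. = FALSE)
  list(marker_idx = marker_idx, control_idx = control_idx)
}

#' Draw a negative-control gene set
#'
#' Samples `n` genes (default 500) uniformly from the genes not in any of
#' the panel's marker lists, using the current RNG state. One control set
#' per run, shared by all cells, keeps control scores comparable.
#'
#' @param panel a `MarkerPanel`.
#' @param gene_ids all gene ids of the matrix.
#' @param n control-set size (default 500; truncated with a warning when
#'   fewer non-marker genes exist).
#' @return The panel with `negative_control` filled in.
#' @export
draw_negative_control <- function(panel, gene_ids, n = 500L) {
  pool <- setdiff(gene_ids, unlist(panel$markers, use.names = FALSE))
  if (length(pool) < n) {
    warning("only ", length(pool), " non-marker genes available for the ",
            "negative control (requested ", n, ")", call. = FALSE)
    n <- length(pool)
  }
  if (n < 1L) stop("no genes left for a negative control", call. = FALSE)
  panel$negative_control <- sample(pool, n)
  panel
}

#' Assign putative cell types to every cell of a matrix
#'
#' Run-level wrapper around [assign_cell_type()]: resolves the panel
#' against the matrix once, draws the shared negative-control set if the
#' panel has none, seeds the RNG, and scores every cell.
#'
#' @param nm a `NormalizedMatrix` from [normalize_counts()].
#' @param panel a `MarkerPanel`.
#' @param thresholds a [typing_thresholds()] object.
#' @param seed integer seed controlling the control-gene draw and all
#'   permutations; `NULL` uses the current RNG state.
#' @param n_control negative-control size when the panel has none.
#' @return Data frame of class `TypingResult`, one row per cell: `barcode`,
#'   `label`, `control_es`, per-type score columns, and
#'   `flagged_inconsistent` (`NA` until [consistency_filter()] is run).
#' @export
assign_cell_types <- function(nm, panel, thresholds = typing_thresholds(),
                              seed = NULL, n_control = 500L) {
  stopifnot(is(nm, "NormalizedMatrix"), is(panel, "MarkerPanel"))
  if (!is.null(seed)) set.seed(seed)
  if (!length(panel$negative_control))
    panel <- draw_negative_control(panel, nm$genes, n_control)
  rp <- resolve_panel(panel, nm$genes)
  n_cells <- nrow(nm$values)
  n_types <- length(panel$types)
  es <- fdr <- frac <- obs <- matrix(0, n_cells, n_types,
                                     dimnames = list(NULL, panel$types))
  ratio_es <- function(observed, bg_mean)
    ifelse(bg_mean == 0, ifelse(observed > 0, Inf, 0), observed / bg_mean)
  for (i in seq_len(n_types)) {
    idx <- rp$marker_idx[[i]]
    sc <- score_marker_set(nm$values, idx, thresholds$n_perm)
    obs[, i] <- sc[, "observed"]
    es[, i] <- ratio_es(sc[, "observed"], sc[, "bg_mean"])
    fdr[, i] <- sc[, "n_exceed"] / thresholds$n_perm
    frac[, i] <- rowMeans(nm$values[, idx, drop = FALSE] > 0)
  }
  csc <- score_marker_set(nm$values, rp$control_idx, thresholds$n_perm)
  control_es <- ratio_es(csc[, "observed"], csc[, "bg_mean"])
  labels <- vapply(seq_len(n_cells), function(c)
    label_from_scores(list(es = es[c, ], fdr = fdr[c, ], frac = frac[c, ],
                           control_es = control_es[c]),
                      panel$types, thresholds),
    character(1))
  out <- data.frame(barcode = nm$barcodes, label = labels,
                    control_es = control_es,
                    flagged_inconsistent = NA,
                    stringsAsFactors = FALSE)
  for (t in panel$types) {
    out[[paste0("es_", t)]] <- es[, t]
    out[[paste0("fdr_", t)]] <- fdr[, t]
    out[[paste0("frac_", t)]] <- frac[, t]
    out[[paste0("mean_", t)]] <- obs[, t]
  }
  attr(out, "thresholds") <- thresholds
  attr(out, "panel") <- panel
  class(out) <- c("TypingResult", "data.frame")
  out
}

#' Flag cells whose embedding position contradicts their label
#'
#' Replaces by an explicit rule the visual step of removing labelled cells
#' that sit apart from the bulk of their type in a 2-D embedding. For each
#' type, its cells are density-clustered in the embedding; cells outside
#' the type's largest cluster are flagged. Additionally all cells are
#' clustered jointly and a cell whose cluster has a different majority
#' label is flagged. Types with fewer cells than `min_cluster_size` are
#' left unflagged (insufficient evidence) with a warning. Flags only;
#' removal is the caller's decision.
#'
#' @param labels character vector of per-cell labels.
#' @param embedding cells x 2 numeric matrix of coordinates.
#' @param min_cluster_size smallest cell group treated as a cluster
#'   (default 100).
#' @param exclude labels never checked (default the two sentinel labels).
#' @param ... passed to [density_cluster()].
#' @return Logical vector of `flagged_inconsistent` per cell.
#' @export
consistency_filter <- function(labels, embedding, min_cluster_size = 100L,
                               exclude = c("random_others", "no_type_match"),
                               ...) {
  embedding <- as.matrix(embedding)
  stopifnot(length(labels) == nrow(embedding), ncol(embedding) == 2L)
  flags <- logical(length(labels))
  types <- setdiff(unique(labels), exclude)
  global_cl <- density_cluster(embedding, min_cluster_size = min_cluster_size,
                               ...)
  for (t in types) {
    cells <- which(labels == t)
    if (length(cells) < min_cluster_size) {
      warning("type '", t, "' has ", length(cells), " cells (< ",
              min_cluster_size, "): left unflagged", call. = FALSE)
      next
    }
    cl <- density_cluster(embedding[cells, , drop = FALSE],
                          min_cluster_size = min_cluster_size, ...)
    in_cluster <- cl[cl > 0L]
    if (!length(in_cluster)) {
      warning("type '", t, "' forms no cluster at min_cluster_size ",
              min_cluster_size, ": left unflagged", call. = FALSE)
      next
    }
    main <- as.integer(names(which.max(table(in_cluster))))
    flags[cells[cl != main]] <- TRUE
    # majority-label check in the joint clustering
    for (g in setdiff(unique(global_cl[cells]), 0L)) {
      members <- global_cl == g
      maj <- names(which.max(table(labels[members])))
      if (maj != t) flags[cells[global_cl[cells] == g]] <- TRUE
    }
  }
  flags
}
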