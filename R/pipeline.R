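#' Nonlinear 2-D embedding of the expression matrix
#'
#' Thin contract over a configurable embedding backend (default
#' \pkg{uwot}'s UMAP) run with this pipeline's standard parameters:
#' `n_neighbors = 100`, `n_components = 2`, `min_dist = 0`, random
#' initialisation, Euclidean metric, fixed random state 123 and 1000
#' epochs. Deterministic given the random state (single-threaded
#' optimisation is forced). `n_neighbors` is clamped to `n - 1` for small
#' matrices, with a warning.
#'
#' @param values cells x genes numeric matrix (normalized expression), or
#'   a `NormalizedMatrix`.
#' @param n_neighbors,n_components,min_dist,init,metric,random_state,n_epochs
#'   embedding parameters (defaults as above).
#' @param backend `"uwot"` (the only built-in backend) or a function
#'   `(values, ...) -> matrix` for plugging in alternatives.
#' @return cells x 2 numeric matrix.
#' @export
embed_cells <- function(values, n_neighbors = 100L, n_components = 2L,
                        min_dist = 0, init = "random",
                        metric = "euclidean", random_state = 123L,
                        n_epochs = 1000L, backend = "uwot") {
  if (is(values, "NormalizedMatrix")) values <- values$values
  values <- as.matrix(values)
  if (nrow(values) < 3L) stop("need at least 3 cells to embed",
                              call. = FALSE)
  if (is.function(backend))
    return(backend(values, n_neighbors = n_neighbors,
                   n_components = n_components, min_dist = min_dist,
                   init = init, metric = metric,
                   random_state = random_state, n_epochs = n_epochs))
  if (!identical(backend, "uwot"))
    stop("unknown embedding backend '", backend,
         "'; install/supply the backend or pass a function", call. = FALSE)
  if (n_neighbors >= nrow(values)) {
    warning("n_neighbors reduced to ", nrow(values) - 1L,
            " for a ", nrow(values), "-cell matrix", call. = FALSE)
    n_neighbors <- nrow(values) - 1L
  }
  set.seed(random_state)
  uwot::umap(values, n_neighbors = n_neighbors,
             n_components = n_components,
             min_dist = max(min_dist, 1e-9), init = init, metric = metric,
             n_epochs = n_epochs, n_threads = 1, n_sgd_threads = 0)
}

#' Density-based clustering of low-dimensional points
#'
#' Default density backend: points are joined into an eps-neighbourhood
#' graph over their `k_neighbors` nearest neighbours and the connected
#' components are the clusters; components smaller than
#' `min_cluster_size` are noise. When `eps` is not given it is set to 3x
#' the 98th percentile of the distance to the 10th nearest neighbour, a
#' scale forgiving enough to keep a density region's tail points attached
#' while leaving well-separated regions apart. Cluster ids are ordered by decreasing size (1 = largest); noise
#' is 0.
#'
#' @param points n x d numeric matrix.
#' @param min_cluster_size smallest group reported as a cluster (default
#'   100).
#' @param eps neighbourhood radius; `NULL` for the automatic heuristic.
#' @param k_neighbors neighbours considered per point (default 20).
#' @return Integer vector of cluster labels, 0 = noise.
#' @export
density_cluster <- function(points, min_cluster_size = 100L, eps = NULL,
                            k_neighbors = 20L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < min_cluster_size) {
    warning("fewer points (", n, ") than min_cluster_size (",
            min_cluster_size, "): all noise", call. = FALSE)
    return(integer(n))
  }
  k <- min(n - 1L, max(k_neighbors, 10L))
  nn <- RANN::nn2(points, k = k + 1L)
  if (is.null(eps)) {
    kd <- nn$nn.dists[, min(11L, k + 1L)]
    eps <- 3 * stats::quantile(kd, 0.98, names = FALSE)
    if (eps == 0) eps <- max(nn$nn.dists) * 1e-6 + .Machine$double.eps
  }
  from <- rep(seq_len(n), k)
  to <- as.vector(nn$nn.idx[, -1L])
  keep <- as.vector(nn$nn.dists[, -1L]) <= eps
  g <- igraph::graph_from_edgelist(cbind(from[keep], to[keep]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  comp <- igraph::components(g)
  sizes <- comp$csize
  big <- which(sizes >= min_cluster_size)
  big <- big[order(sizes[big], decreasing = TRUE)]
  labels <- integer(n)
  for (i in seq_along(big)) labels[comp$membership == big[i]] <- i
  labels
}

#' Density clustering of cells into subtypes
#'
#' Clusters 2-D embedding coordinates (or a PCA-reduced matrix) with the
#' density backend at `min_cluster_size = 100`, the setting used to split
#' spermatocytes and elongating spermatids into stable subtypes; points
#' in no cluster get the noise label 0.
#'
#' @inheritParams density_cluster
#' @return Integer vector of subtype labels, 0 = noise.
#' @export
subtype_cluster <- function(points, min_cluster_size = 100L, ...) {
  density_cluster(points, min_cluster_size = min_cluster_size, ...)
}

#' Pipeline configuration
#'
#' All stage toggles and thresholds of the end-to-end run. The defaults
#' are the pipeline's standard parameter set: cells need at least 500
#' detected genes and genes more than 10 cells; typing uses 1000
#' permutations, a 500-gene negative control, the 20% marker-detection
#' rule, FDR < 0.001 and ES >= 5; marker calling uses p < 1e-10 and
#' log2FC >= 2, DEG calling p < 1e-10 and |log2FC| >= 1; the embedding
#' runs with n_neighbors 100, 2 components, min_dist 0, random
#' initialisation, Euclidean metric, random state 123 and 1000 epochs;
#' subtype clustering uses min_cluster_size 100.
#'
#' @param stages character vector of enabled stages, a subset of
#'   `c("simulate", "prep", "embed", "type", "consistency", "attributes",
#'   "markers", "degs", "subtypes")` (order fixed internally).
#' @param seed master seed; every stochastic stage derives its seed from
#'   it.
#' @param input_dir MTX bundle to read when the simulate stage is off.
#' @param sim simulation configuration ([simulation_config()]).
#' @param min_genes_per_cell,min_cells_per_gene filtering thresholds.
#' @param typing a [typing_thresholds()] object.
#' @param n_control negative-control size.
#' @param embedding named list of [embed_cells()] parameters.
#' @param min_cluster_size subtype/consistency cluster size.
#' @param marker_params,deg_params named lists of caller thresholds.
#' @param condition_a,condition_b condition labels contrasted by the DEG
#'   stage.
#' @return A list of class `PipelineConfig`.
#' @export
pipeline_config <- function(
    stages = c("simulate", "prep", "embed", "type", "consistency",
               "attributes", "markers", "degs", "subtypes"),
    seed = 123L,
    input_dir = NULL,
    sim = simulation_config(),
    min_genes_per_cell = 500L,
    min_cells_per_gene = 10L,
    typing = typing_thresholds(min_marker_fraction = 0.20,
                               max_fdr = 0.001, min_es = 5,
                               n_perm = 1000L),
    n_control = 500L,
    embedding = list(n_neighbors = 100L, n_components = 2L, min_dist = 0,
                     init = "random", metric = "euclidean",
                     random_state = 123L, n_epochs = 1000L),
    min_cluster_size = 100L,
    marker_params = list(min_pct_in = 0.20, min_pct_diff = 0.10,
                         max_p = 1e-10, min_log2fc = 2),
    deg_params = list(max_p = 1e-10, min_abs_log2fc = 1),
    condition_a = "normoxia",
    condition_b = "hypoxia") {
  known <- c("simulate", "prep", "embed", "type", "consistency",
             "attributes", "markers", "degs", "subtypes")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(list(stages = intersect(known, stages), seed = as.integer(seed),
                 input_dir = input_dir, sim = sim,
                 min_genes_per_cell = min_genes_per_cell,
                 min_cells_per_gene = min_cells_per_gene,
                 typing = typing, n_control = n_control,
                 embedding = embedding,
                 min_cluster_size = min_cluster_size,
                 marker_params = marker_params, deg_params = deg_params,
                 condition_a = condition_a, condition_b = condition_b),
            class = "PipelineConfig")
}

config_fingerprint <- function(config) {
  plain <- rapply(unclass(config), unclass, how = "replace")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  unname(tools::md5sum(tmp))
}

write_stage_tsv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# permtyper run manifest ", hash), con)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = NA),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order — simulate (or read), prep
#' (filter + normalize), embed, type, consistency filter, attributes,
#' marker calling, condition DEGs, subtype clustering — writing one TSV
#' per stage, a JSON manifest (package version, seed, thresholds,
#' per-stage row counts, configuration fingerprint) and a log. One master
#' seed controls the generator, the control-gene draw, every permutation
#' and the embedding random state, so re-running the same configuration
#' reproduces byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param verbose print per-stage log lines (default `TRUE`).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         verbose = TRUE) {
  stopifnot(is(config, "PipelineConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_fingerprint(config)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  counts <- list()
  say <- function(stage, msg) {
    line <- sprintf("[%s] %s | %s", stage, msg,
                    format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
    cat(line, "\n", file = log_path, append = TRUE)
    if (verbose) message(line)
  }
  on_stage <- function(s) s %in% config$stages
  res <- list(manifest = NULL)

  run_stage <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    say(stage, sprintf("done in %.1fs", proc.time()[["elapsed"]] - t0))
    out
  }

  raw <- NULL; panel <- NULL
  if (!length(config$stages)) {
    # nothing enabled: emit the manifest alone
  } else if (on_stage("simulate")) {
    sim <- run_stage("simulate",
                     simulate_dataset(config$sim, seed = config$seed))
    raw <- sim$matrix
    panel <- sim$panel
    res$sim <- sim
    counts$simulate <- nrow(raw$counts)
  } else if (!is.null(config$input_dir)) {
    d <- config$input_dir
    raw <- run_stage("read", read_matrix(
      file.path(d, "matrix.mtx"), file.path(d, "barcodes.tsv"),
      file.path(d, "features.tsv"), file.path(d, "annotation.tsv"),
      condition = file.path(d, "conditions.tsv")))
    panel <- NULL
    counts$read <- nrow(raw$counts)
  } else stop("either enable the simulate stage or set input_dir",
              call. = FALSE)
  res$raw <- raw

  nm <- NULL
  typing <- NULL
  emb <- NULL
  if (on_stage("prep")) {
    filtered <- run_stage("prep", {
      f <- filter_cells_genes(raw, config$min_genes_per_cell,
                              config$min_cells_per_gene)
      f
    })
    nm <- normalize_counts(filtered)
    res$filtered <- filtered
    res$normalized <- nm
    counts$prep <- nrow(nm$values)
    rep <- attr(filtered, "filter_report")
    say("prep", sprintf("removed %d cells, %d genes", rep$cells_removed,
                        rep$genes_removed))
  }

  if (on_stage("embed")) {
    if (is.null(nm)) stop("embed stage requires prep", call. = FALSE)
    ep <- config$embedding
    ep$random_state <- config$seed + 1L
    emb <- run_stage("embed", do.call(embed_cells, c(list(nm), ep)))
    res$embedding <- emb
    write_stage_tsv(data.frame(barcode = nm$barcodes, umap1 = emb[, 1L],
                               umap2 = emb[, 2L]),
                    file.path(out_dir, "embedding.tsv"), hash)
    counts$embed <- nrow(emb)
  }

  if (on_stage("type")) {
    if (is.null(nm)) stop("type stage requires prep", call. = FALSE)
    if (is.null(panel)) stop("type stage requires a marker panel (from ",
                             "the simulate stage)", call. = FALSE)
    typing <- run_stage("type", assign_cell_types(
      nm, panel, thresholds = config$typing, seed = config$seed + 2L,
      n_control = config$n_control))
    counts$type <- nrow(typing)
  }

  if (on_stage("consistency") && !is.null(typing) && !is.null(emb)) {
    typing$flagged_inconsistent <- run_stage("consistency",
      consistency_filter(typing$label, emb,
                         min_cluster_size = config$min_cluster_size))
    counts$consistency <- sum(typing$flagged_inconsistent)
  }
  if (!is.null(typing)) {
    res$typing <- typing
    write_stage_tsv(typing, file.path(out_dir, "typing.tsv"), hash)
  }

  if (on_stage("attributes")) {
    if (is.null(nm)) stop("attributes stage requires prep", call. = FALSE)
    labels <- if (!is.null(typing)) typing$label else NULL
    attrs <- run_stage("attributes",
                       cell_attributes(res$filtered, nm, labels = labels))
    res$attributes <- attrs
    write_stage_tsv(attrs, file.path(out_dir, "attributes.tsv"), hash)
    counts$attributes <- nrow(attrs)
  }

  callable_types <- function() {
    tab <- table(typing$label)
    setdiff(names(tab[tab >= 2L]), c("random_others", "no_type_match"))
  }

  if (on_stage("markers") && !is.null(typing)) {
    res$markers <- run_stage("markers", {
      out <- list()
      for (t in callable_types()) {
        if (sum(typing$label != t) < 2L) next
        rec <- do.call(specific_genes,
                       c(list(nm, typing$label, t), config$marker_params))
        out[[t]] <- rec
        write_stage_tsv(rec, file.path(out_dir,
                                       paste0("markers_", t, ".tsv")),
                        hash)
      }
      out
    })
    counts$markers <- sum(vapply(res$markers,
                                 function(r) sum(r$passes), 0L))
  }

  if (on_stage("degs") && !is.null(typing)) {
    res$degs <- run_stage("degs", {
      out <- list()
      for (t in callable_types()) {
        cond <- nm$condition[typing$label == t]
        if (sum(cond == config$condition_a) < 2L ||
            sum(cond == config$condition_b) < 2L) next
        rec <- do.call(condition_degs,
                       c(list(nm, typing$label, t, config$condition_a,
                              config$condition_b), config$deg_params))
        out[[t]] <- rec
        write_stage_tsv(rec, file.path(out_dir, paste0("degs_", t, ".tsv")),
                        hash)
      }
      out
    })
    counts$degs <- sum(vapply(res$degs, function(r) sum(r$passes), 0L))
  }

  if (on_stage("subtypes") && !is.null(typing) && !is.null(emb)) {
    res$subtypes <- run_stage("subtypes", {
      sub <- rep(NA_integer_, nrow(typing))
      for (t in callable_types()) {
        idx <- which(typing$label == t)
        sub[idx] <- suppressWarnings(
          subtype_cluster(emb[idx, , drop = FALSE],
                          min_cluster_size = config$min_cluster_size))
      }
      df <- data.frame(barcode = typing$barcode, label = typing$label,
                       subtype = sub)
      write_stage_tsv(df, file.path(out_dir, "subtypes.tsv"), hash)
      df
    })
    counts$subtypes <- length(unique(stats::na.omit(res$subtypes$subtype)))
  }

  manifest <- list(
    package = "permtyper",
    version = as.character(utils::packageVersion("permtyper")),
    seed = config$seed,
    config_fingerprint = hash,
    stages = config$stages,
    thresholds = list(
      min_genes_per_cell = config$min_genes_per_cell,
      min_cells_per_gene = config$min_cells_per_gene,
      typing = unclass(config$typing),
      n_control = config$n_control,
      marker_params = config$marker_params,
      deg_params = config$deg_params,
      min_cluster_size = config$min_cluster_size,
      embedding = config$embedding),
    stage_counts = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  say("run", "pipeline complete")
  invisible(res)
}
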