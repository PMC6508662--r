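#' Multi-scale partitions
#'
#' A `multiscale_partition` assigns one integer community label to every
#' node-layer of a supra-modularity structure. Labels are canonicalized to
#' `1..C` in order of first appearance and are globally meaningful across
#' layers (and modalities/slices): the multilayer couplings are what make a
#' community at one scale statistically the same object as a community at a
#' neighboring scale.
#'
#' @param labels integer vector, one label per node-layer (flat layout
#'   order of the supra structure).
#' @param b the `supra_modularity` the labels refer to.
#' @param seed optional seed recorded for provenance.
#' @return an object of class `multiscale_partition` with elements `labels`,
#'   `n_nodes`, `n_layers`, `layout`, `quality` (normalized, `Q`),
#'   `quality_raw` (`2 * mu * Q`), and `seed`.
#' @export
multiscale_partition <- function(labels, b, seed = NA_integer_) {
  stopifnot(inherits(b, "supra_modularity"))
  labels <- as.integer(labels)
  if (length(labels) != b$n_node_layers) {
    stop("labels length must equal the number of node-layers")
  }
  labels <- canonicalize_labels(labels)
  qraw <- quality_raw(b, labels)
  structure(
    list(labels = labels,
         n_nodes = max(b$layout$node),
         n_layers = max(b$layout$layer),
         layout = b$layout,
         gamma_grid = .layout_gamma(b),
         quality = qraw / (2 * b$mu),
         quality_raw = qraw,
         seed = seed),
    class = "multiscale_partition"
  )
}

.layout_gamma <- function(b) {
  if (!is.null(b$spec$gamma_grid)) b$spec$gamma_grid else b$spec$gamma_grid_a
}

#' @export
print.multiscale_partition <- function(x, ...) {
  cat(sprintf("<multiscale_partition> %d nodes x %d layers, %d communities, Q = %.6g\n",
              x$n_nodes, x$n_layers, max(x$labels), x$quality))
  invisible(x)
}

#' Canonicalize community labels to 1..C by first appearance
#'
#' @param labels integer vector of community ids.
#' @return integer vector relabeled to `1..C`.
#' @export
canonicalize_labels <- function(labels) {
  match(labels, unique(labels))
}

#' Community labels as a node-by-layer matrix
#'
#' @param p a `multiscale_partition`.
#' @param modality,slice which modality/slice to extract (where applicable).
#' @return integer matrix with one row per node and one column per layer.
#' @export
label_matrix <- function(p, modality = 1L, slice = 1L) {
  lay <- p$layout
  keep <- rep(TRUE, nrow(lay))
  if (!is.null(lay$modality)) keep <- keep & lay$modality == modality
  if (!is.null(lay$slice)) keep <- keep & lay$slice == slice
  lab <- p$labels[keep]
  node <- lay$node[keep]
  layer <- lay$layer[keep]
  m <- matrix(NA_integer_, max(node), max(layer))
  m[cbind(node, layer)] <- lab
  m
}

#' Multi-scale modularity of a partition
#'
#' Scores a community assignment against a supra-modularity structure:
#' `Q = (1 / 2mu) * sum B[(i,x),(j,y)] * delta(g_ix, g_jy)` over ordered
#' pairs of distinct node-layers. Pure function of its inputs.
#'
#' @param b a `supra_modularity`.
#' @param p a `multiscale_partition`, or a bare integer label vector.
#' @return scalar quality `Q`.
#' @export
evaluate_quality <- function(b, p) {
  labels <- if (inherits(p, "multiscale_partition")) p$labels else as.integer(p)
  quality_raw(b, labels) / (2 * b$mu)
}

#' @rdname evaluate_quality
#' @param labels integer label vector over node-layers.
#' @return `quality_raw`: the unnormalized score `2 * mu * Q`.
#' @export
quality_raw <- function(b, labels) {
  stopifnot(inherits(b, "supra_modularity"))
  if (length(labels) != b$n_node_layers) {
    stop("dimension mismatch between partition and supra structure")
  }
  tm <- methods::as(b$matrix, "TsparseMatrix")
  sum(tm@x[labels[tm@i + 1L] == labels[tm@j + 1L]])
}

#' Generalized Louvain optimization of a supra-modularity structure
#'
#' Locally greedy maximization: nodes are visited in a seeded uniform
#' shuffle (reshuffled every pass) and moved to the neighboring (or empty)
#' community with the largest quality gain, ties broken toward the lowest
#' community id; when no single move helps, communities are aggregated into
#' super-nodes and the procedure repeats. Moves are accepted only when they
#' improve the raw quality by more than `tol` (1e-12), which prevents
#' floating-point cycling. Quality is non-decreasing across every phase
#' (asserted internally) and the recorded quality is re-derived from the
#' returned labels. Identical `(b, seed)` give identical output.
#'
#' @param b a `supra_modularity`.
#' @param seed integer seed for the visiting order.
#' @param tol minimum raw-quality improvement for accepting a move.
#' @return a `multiscale_partition`; the per-phase raw qualities are
#'   attached as attribute `"phase_q"`.
#' @export
louvain_optimize <- function(b, seed = 1L, tol = 1e-12) {
  stopifnot(inherits(b, "supra_modularity"))
  bm <- methods::as(b$matrix, "CsparseMatrix")
  set.seed(seed)
  res <- genlouvain_cpp(bm@p, bm@i, bm@x, b$n_node_layers, tol)
  part <- multiscale_partition(res$labels, b, seed = seed)
  if (abs(part$quality_raw - res$q_raw) > 1e-6 * (1 + abs(res$q_raw))) {
    stop("internal error: optimizer quality does not match evaluate_quality")
  }
  attr(part, "phase_q") <- res$phase_q
  part
}

#' Repeated seeded optimizations of one supra-modularity problem
#'
#' The modularity landscape is degenerate, so statistics are built over an
#' ensemble of independent optimizations (100 by default elsewhere in the
#' package) rather than a single run. Runs use seeds
#' `base_seed .. base_seed + n_runs - 1` and are fully reproducible.
#'
#' @param b a `supra_modularity`.
#' @param n_runs number of optimizations (>= 1).
#' @param base_seed first seed.
#' @return an object of class `partition_ensemble`: list with `runs` (list
#'   of `multiscale_partition`), `seeds`, and the layout metadata.
#' @export
run_ensemble <- function(b, n_runs = 100L, base_seed = 1L) {
  stopifnot(inherits(b, "supra_modularity"))
  if (n_runs < 1L) stop("n_runs must be >= 1")
  seeds <- base_seed + seq_len(n_runs) - 1L
  runs <- lapply(seeds, function(s) louvain_optimize(b, seed = s))
  structure(list(runs = runs, seeds = seeds,
                 n_nodes = runs[[1L]]$n_nodes,
                 n_layers = runs[[1L]]$n_layers,
                 layout = b$layout,
                 gamma_grid = .layout_gamma(b)),
            class = "partition_ensemble")
}

#' @export
print.partition_ensemble <- function(x, ...) {
  cat(sprintf("<partition_ensemble> %d runs, %d nodes x %d layers\n",
              length(x$runs), x$n_nodes, x$n_layers))
  invisible(x)
}

#' Independent single-layer sweep over a gamma grid
#'
#' The baseline that the multi-scale chain improves upon: one single-layer
#' modularity problem per gamma value, optimized independently. Community
#' labels at different gamma values are unrelated (the correspondence
#' problem) -- no attempt is made to link them.
#'
#' @param g a [weighted_graph()].
#' @param gamma_grid numeric vector of resolution values.
#' @param null a [null_model()].
#' @param n_runs restarts per gamma value; the best-quality run is kept.
#' @param base_seed seed for the first restart of the first gamma.
#' @return a list with one element per gamma value, each a
#'   `multiscale_partition` over a single layer.
#' @export
single_scale_sweep <- function(g, gamma_grid, null, n_runs = 1L, base_seed = 1L) {
  stopifnot(inherits(g, "weighted_graph"))
  out <- vector("list", length(gamma_grid))
  seed <- base_seed
  for (k in seq_along(gamma_grid)) {
    spec <- multiscale_spec(g, gamma_grid[k], tau = 0, null = null)
    b <- build_multiscale(spec)
    best <- NULL
    for (r in seq_len(n_runs)) {
      cand <- louvain_optimize(b, seed = seed)
      seed <- seed + 1L
      if (is.null(best) || cand$quality_raw > best$quality_raw) best <- cand
    }
    out[[k]] <- best
  }
  names(out) <- paste0("gamma_", signif(gamma_grid, 10))
  out
}

#' Write and read partitions as TSV plus a JSON sidecar
#'
#' The TSV has columns `node`, `layer` (plus `modality`/`slice` where the
#' layout has them) and `community`; the sidecar records the quality, the
#' seed, and a hash of the generating spec so artifacts can be validated
#' against their configuration.
#'
#' @param p a `multiscale_partition`.
#' @param path output TSV path; the sidecar is written at `<path>.json`.
#' @param spec_hash hash string tying the artifact to its run configuration.
#' @return `write_partition_tsv` returns `path` invisibly;
#'   `read_partition_tsv` returns a list with `table` (data.frame) and
#'   `meta` (sidecar contents, when present).
#' @export
write_partition_tsv <- function(p, path, spec_hash = NULL) {
  stopifnot(inherits(p, "multiscale_partition"))
  df <- cbind(p$layout, community = p$labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(quality = p$quality, quality_raw = p$quality_raw,
               seed = p$seed, spec_hash = spec_hash)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_partition_tsv
#' @export
read_partition_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::fromJSON(meta_path) else NULL
  list(table = tab, meta = meta)
}
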