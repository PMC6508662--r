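#' Construct a weighted graph from a symmetric nonnegative matrix
#'
#' The basic data container of the package: an undirected weighted graph on
#' `n` nodes stored as a symmetric, nonnegative `n x n` matrix with a zero
#' diagonal. The matrix houses the adjacency weights `A[i, j]` that enter
#' every modularity quality function in the package.
#'
#' Input matrices are validated, not silently repaired: asymmetry within
#' `asym_tol` (absolute) is averaged away -- this tolerates float round-trip
#' noise from text serialization -- while larger asymmetry is an error, as are
#' self-loops (nonzero diagonal), negative weights, and non-finite entries.
#'
#' @param weights square numeric matrix of edge weights.
#' @param node_labels optional character vector of node names (defaults to
#'   the matrix dimnames when present).
#' @param asym_tol maximum absolute asymmetry `|W - t(W)|` that is averaged
#'   rather than rejected.
#' @return an object of class `weighted_graph` with elements `n_nodes`,
#'   `weights`, and `node_labels`.
#' @export
weighted_graph <- function(weights, node_labels = NULL, asym_tol = 1e-10) {
  weights <- as.matrix(weights)
  if (!is.numeric(weights)) stop("weights must be a numeric matrix")
  n <- nrow(weights)
  if (ncol(weights) != n) stop("weights must be square")
  if (n < 1L) stop("graph must have at least one node")
  if (any(!is.finite(weights))) stop("weights must all be finite")
  asym <- max(abs(weights - t(weights)))
  if (asym > asym_tol) {
    stop(sprintf("weights matrix is asymmetric (max |W - t(W)| = %.3g > tolerance %.3g)",
                 asym, asym_tol))
  }
  if (asym > 0) weights <- (weights + t(weights)) / 2
  if (any(diag(weights) != 0)) stop("self-loops are not allowed (diagonal must be zero)")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (is.null(node_labels) && !is.null(rownames(weights))) {
    node_labels <- rownames(weights)
  }
  if (!is.null(node_labels)) {
    node_labels <- as.character(node_labels)
    if (length(node_labels) != n) stop("node_labels length must equal number of nodes")
    dimnames(weights) <- list(node_labels, node_labels)
  } else {
    dimnames(weights) <- NULL
  }
  structure(
    list(n_nodes = n, weights = weights, node_labels = node_labels),
    class = "weighted_graph"
  )
}

#' @export
print.weighted_graph <- function(x, ...) {
  ne <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("<weighted_graph> %d nodes, %d positive edges, total weight %.4g\n",
              x$n_nodes, ne, sum(x$weights) / 2))
  invisible(x)
}

#' Log-transform edge weights to a unit maximum
#'
#' Applies `log(w + 1) / max(log(w + 1))` to every weight. This is the
#' standard compression used for heavy-tailed streamline-count matrices
#' before community detection: zeros stay zero, the order of weights is
#' preserved, and the strongest edge is mapped to exactly 1.
#'
#' @param g a [weighted_graph()].
#' @return a `weighted_graph` with transformed weights.
#' @export
log_transform_weights <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  w <- g$weights
  if (all(w == 0)) stop("all weights are zero: log-transform normalizer undefined")
  lw <- log1p(w)
  lw <- lw / max(lw)
  weighted_graph(lw, node_labels = g$node_labels)
}

#' Uniform-null constants derived from a graph's weights
#'
#' Returns the constant used by the uniform (geographic / constant Potts)
#' null model. Three conventions are provided because the right choice
#' depends on the data type: for sparse streamline-count-like matrices the
#' smallest positive weight is stable across subjects (`min_positive`),
#' whereas for dense coherence-like matrices the mean is the stable summary
#' (`mean_nonzero` over positive entries, or `mean_all` over every
#' off-diagonal entry including zeros).
#'
#' @param g a [weighted_graph()].
#' @param mode one of `"min_positive"`, `"mean_nonzero"`, `"mean_all"`.
#' @return a positive scalar.
#' @export
null_constant <- function(g, mode = c("min_positive", "mean_nonzero", "mean_all")) {
  stopifnot(inherits(g, "weighted_graph"))
  mode <- match.arg(mode)
  if (g$n_nodes < 2L) stop("graph has no off-diagonal entries")
  off <- g$weights[row(g$weights) != col(g$weights)]
  pos <- off[off > 0]
  if (mode %in% c("min_positive", "mean_nonzero") && length(pos) == 0L) {
    stop("graph has no positive weights")
  }
  switch(mode,
    min_positive = min(pos),
    mean_nonzero = mean(pos),
    mean_all     = mean(off)
  )
}

#' Null models for modularity maximization
#'
#' Defines the expected edge weight `P[i, j]` subtracted (scaled by the
#' resolution parameter gamma) from the adjacency weights in the modularity
#' quality function.
#'
#' * `newman_girvan`: `P[i, j] = k_i * k_j / (2m)` where `k_i` is the
#'   strength of node `i` and `m` is half the total weight. Expectation
#'   under a strength-preserving random rewiring.
#' * `uniform`: `P[i, j] = constant` for all `i != j` (geographic null /
#'   constant Potts model). Keeps a one-to-one relationship between edge
#'   weight and the topological scale at which a community dissolves,
#'   irrespective of node degree.
#'
#' @param kind `"newman_girvan"` or `"uniform"`.
#' @param constant positive constant expected weight (`uniform` only). May be
#'   omitted when `mode` is given.
#' @param mode optional [null_constant()] mode; when given, the constant is
#'   derived from the graph at [null_expected_matrix()] time.
#' @return an object of class `null_model`.
#' @export
null_model <- function(kind = c("newman_girvan", "uniform"), constant = NULL,
                       mode = NULL) {
  kind <- match.arg(kind)
  if (kind == "uniform") {
    if (is.null(constant) && is.null(mode)) {
      stop("uniform null model needs a positive `constant` or a `mode`")
    }
    if (!is.null(constant) && (!is.numeric(constant) || constant <= 0)) {
      stop("uniform null constant must be a positive real")
    }
    if (!is.null(mode)) {
      mode <- match.arg(mode, c("min_positive", "mean_nonzero", "mean_all"))
    }
  } else {
    constant <- NULL
    mode <- NULL
  }
  structure(list(kind = kind, constant = constant, mode = mode),
            class = "null_model")
}

#' Expected-weight matrix of a null model on a graph
#'
#' @param null a [null_model()].
#' @param g a [weighted_graph()].
#' @return an `n x n` matrix of expected edge weights `P` (zero diagonal).
#' @export
null_expected_matrix <- function(null, g) {
  stopifnot(inherits(null, "null_model"), inherits(g, "weighted_graph"))
  n <- g$n_nodes
  if (null$kind == "newman_girvan") {
    k <- rowSums(g$weights)
    two_m <- sum(g$weights)
    if (two_m <= 0) stop("Newman-Girvan null undefined on an all-zero graph")
    p <- outer(k, k) / two_m
  } else {
    const <- if (!is.null(null$constant)) null$constant else null_constant(g, null$mode)
    p <- matrix(const, n, n)
  }
  diag(p) <- 0
  p
}

# precision used for text round-trips; %.17g preserves doubles exactly
.fmt_num <- function(x) sprintf("%.17g", x)

#' Read and write graphs as plain-text matrices and edge lists
#'
#' `write_graph_tsv`/`read_graph_tsv` handle a dense matrix with an optional
#' header row of node labels; `write_edge_list`/`read_edge_list` handle a
#' 3-column (node_a, node_b, weight) TSV listing each undirected edge once.
#' Round-tripping reproduces weights to better than 1e-12.
#'
#' @param g a [weighted_graph()].
#' @param path file path.
#' @param sep field separator (tab by default; use "," for CSV).
#' @return `read_*` return a `weighted_graph`; `write_*` return `path`
#'   invisibly.
#' @name graph_io
NULL

#' @rdname graph_io
#' @export
write_graph_tsv <- function(g, path, sep = "\t") {
  stopifnot(inherits(g, "weighted_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(g$node_labels)) {
    writeLines(paste(g$node_labels, collapse = sep), con)
  }
  apply(g$weights, 1L, function(r) writeLines(paste(.fmt_num(r), collapse = sep), con))
  invisible(path)
}

#' @rdname graph_io
#' @export
read_graph_tsv <- function(path, sep = "\t") {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty graph file: ", path)
  first <- strsplit(lines[[1L]], sep, fixed = TRUE)[[1L]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  labels <- NULL
  if (has_header) {
    labels <- first
    lines <- lines[-1L]
  }
  rows <- lapply(seq_along(lines), function(idx) {
    fields <- strsplit(lines[[idx]], sep, fixed = TRUE)[[1L]]
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals))) {
      bad <- which(is.na(vals))[1L]
      stop(sprintf("malformed matrix in '%s': row %d, column %d is not numeric",
                   path, idx, bad))
    }
    vals
  })
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L) {
    stop(sprintf("malformed matrix in '%s': row %d has %d columns, expected %d",
                 path, which(ncols != ncols[1L])[1L],
                 ncols[which(ncols != ncols[1L])[1L]], ncols[1L]))
  }
  w <- do.call(rbind, rows)
  if (nrow(w) != ncol(w)) {
    stop(sprintf("malformed matrix in '%s': %d rows but %d columns",
                 path, nrow(w), ncol(w)))
  }
  weighted_graph(w, node_labels = labels)
}

#' @rdname graph_io
#' @export
write_edge_list <- function(g, path, sep = "\t") {
  stopifnot(inherits(g, "weighted_graph"))
  labs <- g$node_labels %||% as.character(seq_len(g$n_nodes))
  idx <- which(upper.tri(g$weights) & g$weights > 0, arr.ind = TRUE)
  df <- data.frame(node_a = labs[idx[, 1L]], node_b = labs[idx[, 2L]],
                   weight = .fmt_num(g$weights[idx]))
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname graph_io
#' @param node_labels optional full node set (so isolated nodes survive the
#'   round trip); defaults to the labels present in the file, in order of
#'   first appearance.
#' @export
read_edge_list <- function(path, sep = "\t", node_labels = NULL) {
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = c("character", "character", "numeric"))
  if (ncol(df) != 3L) stop("edge list must have 3 columns (node_a, node_b, weight)")
  labs <- node_labels %||% unique(c(rbind(df[[1L]], df[[2L]])))
  n <- length(labs)
  w <- matrix(0, n, n)
  ia <- match(df[[1L]], labs)
  ib <- match(df[[2L]], labs)
  if (any(is.na(ia)) || any(is.na(ib))) stop("edge list names missing from node_labels")
  w[cbind(ia, ib)] <- df[[3L]]
  w[cbind(ib, ia)] <- df[[3L]]
  weighted_graph(w, node_labels = labs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
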