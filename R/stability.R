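#' Node stability across topological scales
#'
#' For node `i` at layer `x` holding community label `X`, stability is the
#' number of layers in which node `i` carries label `X`, divided by the
#' total number of layers `L`. Replacing every label in the node-by-layer
#' label matrix with this fraction gives the stability matrix: high values
#' mean the node keeps one community across a wide range of scales, and
#' diverse row patterns indicate topological heterogeneity of the graph.
#'
#' Because a node's distinct communities partition its layer set, summing a
#' node's stability once per distinct community it ever joins gives exactly
#' 1 -- a conservation identity used in the tests.
#'
#' @param p a `multiscale_partition`.
#' @param modality,slice which modality/slice to analyze (where applicable).
#' @return an object of class `stability_matrix`: list with `values`
#'   (node x layer matrix in `(0, 1]`), `labels` (the underlying label
#'   matrix), and `n_layers`.
#' @export
stability_matrix <- function(p, modality = 1L, slice = 1L) {
  stopifnot(inherits(p, "multiscale_partition"))
  labs <- label_matrix(p, modality = modality, slice = slice)
  l <- ncol(labs)
  vals <- t(apply(labs, 1L, function(r) {
    counts <- table(r)
    as.numeric(counts[as.character(r)]) / l
  }))
  if (l == 1L) vals <- matrix(vals, ncol = 1L)
  structure(list(values = vals, labels = labs, n_layers = l),
            class = "stability_matrix")
}

#' @export
print.stability_matrix <- function(x, ...) {
  cat(sprintf("<stability_matrix> %d nodes x %d layers, mean stability %.3f\n",
              nrow(x$values), x$n_layers, mean(x$values)))
  invisible(x)
}

#' Per-node layer spans of every community a node joins
#'
#' @param s a [stability_matrix()].
#' @return list, one element per node, of named integer vectors: the number
#'   of layers the node spends in each distinct community (names are
#'   community labels). Spans count all layers carrying the label,
#'   contiguous or not.
#' @export
node_community_spans <- function(s) {
  stopifnot(inherits(s, "stability_matrix"))
  apply(s$labels, 1L, function(r) {
    tab <- table(r)
    stats::setNames(as.integer(tab), names(tab))
  }, simplify = FALSE)
}

#' Count stable communities per node at a stability threshold
#'
#' A community is stable for a node when the node belongs to it across more
#' than `threshold_pct` percent of the gamma range studied. Counting the
#' stable communities per node while sweeping the threshold yields the
#' characteristic step curves that distinguish deeply hierarchical graphs
#' (many stable communities over a wide threshold range) from flat ones.
#'
#' @param s a [stability_matrix()].
#' @param threshold_pct stability threshold in percent, in `[0, 100]`.
#' @param include_singletons count communities in which the node is alone in
#'   every layer it holds the label? Both conventions are defensible, so the
#'   choice is exposed; `TRUE` by default.
#' @return integer vector of per-node counts; non-increasing in
#'   `threshold_pct`.
#' @export
count_stable_communities <- function(s, threshold_pct, include_singletons = TRUE) {
  stopifnot(inherits(s, "stability_matrix"))
  if (threshold_pct < 0 || threshold_pct > 100) {
    stop("threshold_pct must lie in [0, 100]")
  }
  l <- s$n_layers
  labs <- s$labels
  if (!include_singletons) {
    # community is a singleton for the node if no layer has a co-member
    comm_sizes <- apply(labs, 2L, function(col) {
      tab <- table(col)
      as.integer(tab[as.character(col)])
    })
    if (l == 1L) comm_sizes <- matrix(comm_sizes, ncol = 1L)
  }
  vapply(seq_len(nrow(labs)), function(i) {
    spans <- table(labs[i, ])
    keep <- as.numeric(spans) / l * 100 > threshold_pct
    if (!include_singletons) {
      shared <- vapply(names(spans), function(lb) {
        any(comm_sizes[i, labs[i, ] == as.integer(lb)] >= 2L)
      }, logical(1L))
      keep <- keep & shared
    }
    sum(keep)
  }, integer(1L))
}

#' Community number and size curves across layers
#'
#' Per layer: the number of non-singleton communities and their mean size
#' expressed as a percentage of the number of nodes (0 when a layer has no
#' non-singleton community). These are the characteristic curves whose rise
#' and fall summarize how a graph's communities branch toward singletons as
#' the resolution increases.
#'
#' @param p a `multiscale_partition`.
#' @param modality,slice which modality/slice to analyze.
#' @return data.frame with columns `layer`, `gamma` (when known),
#'   `n_nonsingleton`, `mean_size_pct`.
#' @export
community_size_curves <- function(p, modality = 1L, slice = 1L) {
  stopifnot(inherits(p, "multiscale_partition"))
  labs <- label_matrix(p, modality = modality, slice = slice)
  n <- nrow(labs)
  per_layer <- lapply(seq_len(ncol(labs)), function(x) {
    sizes <- as.integer(table(labs[, x]))
    ns <- sizes[sizes >= 2L]
    data.frame(layer = x,
               n_nonsingleton = length(ns),
               mean_size_pct = if (length(ns)) mean(ns) / n * 100 else 0)
  })
  out <- do.call(rbind, per_layer)
  gg <- p$gamma_grid
  if (!is.null(gg) && length(gg) == nrow(out)) {
    out <- cbind(out[, "layer", drop = FALSE], gamma = gg,
                 out[, c("n_nonsingleton", "mean_size_pct")])
  }
  out
}

#' Allegiance matrices of a partition ensemble
#'
#' Intra-layer allegiance: for each layer, the fraction of optimizations in
#' which nodes `i` and `j` share a community at that layer. Inter-layer
#' allegiance: for each node, the fraction of optimizations in which it
#' keeps the same community label across two neighboring layers. Both live
#' in `[0, 1]`; intra-layer matrices are symmetric with unit diagonal.
#'
#' @param e a `partition_ensemble`.
#' @param modality,slice which modality/slice to analyze.
#' @return an object of class `allegiance_set`: list with `intra` (list of
#'   `N x N` matrices, one per layer), `inter` (`N x (L - 1)` matrix),
#'   `n_runs`, and `gamma_grid`.
#' @export
allegiance <- function(e, modality = 1L, slice = 1L) {
  stopifnot(inherits(e, "partition_ensemble"))
  if (length(e$runs) < 1L) stop("ensemble is empty")
  mats <- lapply(e$runs, label_matrix, modality = modality, slice = slice)
  n <- nrow(mats[[1L]])
  l <- ncol(mats[[1L]])
  r <- length(mats)
  intra <- vector("list", l)
  for (x in seq_len(l)) {
    acc <- matrix(0, n, n)
    for (m in mats) {
      acc <- acc + outer(m[, x], m[, x], "==")
    }
    intra[[x]] <- acc / r
  }
  inter <- matrix(0, n, max(l - 1L, 0L))
  if (l > 1L) {
    for (x in seq_len(l - 1L)) {
      acc <- numeric(n)
      for (m in mats) acc <- acc + (m[, x] == m[, x + 1L])
      inter[, x] <- acc / r
    }
  }
  structure(list(intra = intra, inter = inter, n_runs = r,
                 gamma_grid = e$gamma_grid),
            class = "allegiance_set")
}

#' @export
print.allegiance_set <- function(x, ...) {
  cat(sprintf("<allegiance_set> %d layers, %d nodes, %d runs\n",
              length(x$intra), nrow(x$intra[[1L]]), x$n_runs))
  invisible(x)
}

#' Topological heterogeneity as a principal-component count
#'
#' Decomposes the node-by-layer stability matrix with PCA (layers centered,
#' covariance on the centered matrix, explained variance from squared
#' singular values) and returns the smallest number of components whose
#' cumulative explained variance reaches `variance_pct` percent. Homogeneous
#' graphs need few components (most nodes share one stability profile);
#' heterogeneous graphs need many.
#'
#' @param s a [stability_matrix()].
#' @param variance_pct target cumulative explained variance, in percent.
#' @return integer component count; 0 (with a warning) when the stability
#'   matrix is exactly constant after centering.
#' @export
heterogeneity_pca <- function(s, variance_pct = 95) {
  stopifnot(inherits(s, "stability_matrix"))
  if (s$n_layers < 2L) stop("PCA over layers needs at least 2 layers")
  x <- s$values
  xc <- scale(x, center = TRUE, scale = FALSE)
  if (all(abs(xc) < .Machine$double.eps * 100)) {
    warning("stability matrix is constant: zero variance, returning 0 components")
    return(0L)
  }
  sv <- svd(xc)$d
  ev <- sv^2 / sum(sv^2) * 100
  as.integer(which(cumsum(ev) >= variance_pct)[1L])
}
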