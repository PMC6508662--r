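#' Evenly spaced structural-resolution (gamma) grids
#'
#' Builds the gamma values assigned to the layers of the multi-scale chain:
#' `start, start + step, ...` up to `stop` inclusive. The endpoint test uses
#' a relative tolerance of `step * 1e-9` so that grids whose step is not
#' exactly representable in binary floating point (for example 0.0133) keep
#' their intended number of layers.
#'
#' @param start,stop grid limits, `start <= stop`.
#' @param step positive increment between neighboring layers.
#' @return strictly increasing numeric vector of gamma values.
#' @export
make_gamma_grid <- function(start, stop, step) {
  if (!is.numeric(step) || length(step) != 1L || step <= 0) {
    stop("step must be a positive real")
  }
  if (start > stop) stop("start must not exceed stop")
  k_max <- floor((stop - start) / step + 1e-9)
  start + step * (0:k_max)
}

#' Specification of a multi-scale (gamma-chain) modularity problem
#'
#' Bundles a graph, a strictly increasing gamma grid (one resolution value
#' per layer), the topological-scale coupling `tau` (a single value applied
#' to every node between each pair of adjacent layers), and a null model.
#'
#' @param graph a [weighted_graph()].
#' @param gamma_grid strictly increasing numeric vector, length >= 1.
#' @param tau nonnegative inter-layer coupling weight.
#' @param null a [null_model()].
#' @return an object of class `multiscale_spec`.
#' @export
multiscale_spec <- function(graph, gamma_grid, tau, null) {
  stopifnot(inherits(graph, "weighted_graph"), inherits(null, "null_model"))
  if (length(gamma_grid) < 1L || any(diff(gamma_grid) <= 0)) {
    stop("gamma_grid must be strictly increasing with length >= 1")
  }
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0) {
    stop("tau must be a nonnegative real")
  }
  structure(list(graph = graph, gamma_grid = as.numeric(gamma_grid),
                 tau = tau, null = null),
            class = "multiscale_spec")
}

#' Specification of a two-modality multiplex multi-scale problem
#'
#' Two graphs over the same node set (for example structural and functional
#' connectivity) each get their own gamma chain and null model; copies of a
#' node at the same scale layer are coupled across modalities with weight
#' `kappa`.
#'
#' @param graph_a,graph_b [weighted_graph()]s over the same node set.
#' @param gamma_grid_a,gamma_grid_b per-modality gamma grids of equal length.
#' @param tau nonnegative inter-layer (scale) coupling, shared.
#' @param kappa nonnegative inter-modality coupling.
#' @param null_a,null_b per-modality [null_model()]s.
#' @return an object of class `multiplex_spec`.
#' @export
multiplex_spec <- function(graph_a, graph_b, gamma_grid_a, gamma_grid_b,
                           tau, kappa, null_a, null_b) {
  stopifnot(inherits(graph_a, "weighted_graph"),
            inherits(graph_b, "weighted_graph"))
  if (graph_a$n_nodes != graph_b$n_nodes) {
    stop("multiplex graphs must share the same node set")
  }
  if (length(gamma_grid_a) != length(gamma_grid_b)) {
    stop("per-modality gamma grids must have equal length")
  }
  if (any(diff(gamma_grid_a) <= 0) || any(diff(gamma_grid_b) <= 0)) {
    stop("gamma grids must be strictly increasing")
  }
  if (tau < 0 || kappa < 0) stop("tau and kappa must be nonnegative")
  structure(list(graph_a = graph_a, graph_b = graph_b,
                 gamma_grid_a = as.numeric(gamma_grid_a),
                 gamma_grid_b = as.numeric(gamma_grid_b),
                 tau = tau, kappa = kappa,
                 null_a = null_a, null_b = null_b),
            class = "multiplex_spec")
}

#' Specification of a multi-slice multi-scale problem
#'
#' An ordered sequence of graph slices (for example time windows) is swept
#' through the same gamma chain; copies of a node are coupled with `omega`
#' across adjacent slices at the same scale layer and with `tau` across
#' adjacent scale layers within the same slice.
#'
#' @param slices list of [weighted_graph()]s sharing a node set.
#' @param gamma_grid strictly increasing gamma grid over scale layers.
#' @param tau nonnegative inter-scale coupling.
#' @param omega nonnegative inter-slice coupling.
#' @param nulls a single [null_model()] applied to every slice, or a list of
#'   one null model per slice.
#' @return an object of class `multislice_spec`.
#' @export
multislice_spec <- function(slices, gamma_grid, tau, omega, nulls) {
  if (!is.list(slices) || length(slices) < 1L ||
      !all(vapply(slices, inherits, logical(1L), "weighted_graph"))) {
    stop("slices must be a nonempty list of weighted_graph objects")
  }
  ns <- vapply(slices, function(s) s$n_nodes, integer(1L))
  if (length(unique(ns)) != 1L) stop("all slices must share the same node set")
  if (length(gamma_grid) < 1L || any(diff(gamma_grid) <= 0)) {
    stop("gamma_grid must be strictly increasing with length >= 1")
  }
  if (tau < 0 || omega < 0) stop("tau and omega must be nonnegative")
  if (inherits(nulls, "null_model")) nulls <- rep(list(nulls), length(slices))
  if (length(nulls) != length(slices)) stop("need one null model per slice")
  structure(list(slices = slices, gamma_grid = as.numeric(gamma_grid),
                 tau = tau, omega = omega, nulls = nulls),
            class = "multislice_spec")
}

# assemble a supra_modularity object from triplets
.supra <- function(ii, jj, xx, n_node_layers, mu, layout, spec, kind) {
  keep <- xx != 0
  b <- Matrix::sparseMatrix(i = c(ii[keep], jj[keep]),
                            j = c(jj[keep], ii[keep]),
                            x = c(xx[keep], xx[keep]),
                            dims = c(n_node_layers, n_node_layers))
  structure(list(matrix = b, mu = mu, n_node_layers = n_node_layers,
                 layout = layout, spec = spec, kind = kind),
            class = "supra_modularity")
}

#' @export
print.supra_modularity <- function(x, ...) {
  cat(sprintf("<supra_modularity> (%s) %d node-layers, %d stored coefficients, mu = %.6g\n",
              x$kind, x$n_node_layers, Matrix::nnzero(x$matrix), x$mu))
  invisible(x)
}

#' Look up a supra-modularity coefficient
#'
#' Behaves as if the dense coefficient matrix existed: entries that are not
#' materialized (cross-layer terms other than chain couplings, diagonal) are
#' zero.
#'
#' @param b a `supra_modularity`.
#' @param node_i,node_j node indices (1-based).
#' @param layer_x,layer_y scale-layer indices.
#' @param modality_i,modality_j modality indices (multiplex only).
#' @param slice_i,slice_j slice indices (multi-slice only).
#' @return scalar coefficient `B((i,x),(j,y))`.
#' @export
supra_coef <- function(b, node_i, layer_x, node_j, layer_y,
                       modality_i = 1L, modality_j = 1L,
                       slice_i = 1L, slice_j = 1L) {
  p <- supra_index(b, node_i, layer_x, modality_i, slice_i)
  q <- supra_index(b, node_j, layer_y, modality_j, slice_j)
  as.numeric(b$matrix[p, q])
}

#' Flat index of a (node, layer, modality/slice) copy
#'
#' @inheritParams supra_coef
#' @param node,layer,modality,slice coordinates of the node copy.
#' @return integer index into the supra-modularity layout.
#' @export
supra_index <- function(b, node, layer, modality = 1L, slice = 1L) {
  lay <- b$layout
  hit <- lay$node == node & lay$layer == layer
  if (!is.null(lay$modality)) hit <- hit & lay$modality == modality
  if (!is.null(lay$slice)) hit <- hit & lay$slice == slice
  idx <- which(hit)
  if (length(idx) != 1L) stop("coordinates not found in supra layout")
  idx
}

# triplets for one gamma chain over a single graph; offset shifts flat indices
.chain_triplets <- function(w, p, gamma_grid, tau, offset = 0L) {
  n <- nrow(w)
  l <- length(gamma_grid)
  off <- which(row(w) != col(w))
  oi <- ((off - 1L) %% n) + 1L
  oj <- ((off - 1L) %/% n) + 1L
  keep <- oi < oj  # store each unordered pair once; .supra symmetrizes
  oi <- oi[keep]; oj <- oj[keep]
  wv <- w[cbind(oi, oj)]
  pv <- p[cbind(oi, oj)]
  ii <- jj <- integer(0); xx <- numeric(0)
  for (x in seq_len(l)) {
    base <- offset + (x - 1L) * n
    ii <- c(ii, base + oi)
    jj <- c(jj, base + oj)
    xx <- c(xx, wv - gamma_grid[x] * pv)
  }
  if (l > 1L && tau > 0) {
    for (x in seq_len(l - 1L)) {
      ii <- c(ii, offset + (x - 1L) * n + seq_len(n))
      jj <- c(jj, offset + x * n + seq_len(n))
      xx <- c(xx, rep(tau, n))
    }
  }
  list(i = ii, j = jj, x = xx)
}

#' Assemble the supra-modularity coefficients of a gamma chain
#'
#' Builds the node-layer coefficient structure whose partition score is the
#' multi-scale modularity: within layer `x` the off-diagonal coefficients are
#' `A[i, j] - gamma_x * P[i, j]`, and each node is coupled to its own copy in
#' the two adjacent layers with weight `tau` (chain topology; no couplings
#' beyond neighboring scales). The normalization `2 * mu` counts every
#' node-layer's strength `K = k + c`, i.e. intra-layer strength plus the
#' coupling weight attached to the node copy.
#'
#' @param spec a [multiscale_spec()].
#' @return a `supra_modularity` object.
#' @export
build_multiscale <- function(spec) {
  stopifnot(inherits(spec, "multiscale_spec"))
  g <- spec$graph
  n <- g$n_nodes
  l <- length(spec$gamma_grid)
  p <- null_expected_matrix(spec$null, g)
  tr <- .chain_triplets(g$weights, p, spec$gamma_grid, spec$tau)
  m <- sum(g$weights) / 2
  mu <- l * m + n * (l - 1L) * spec$tau
  layout <- data.frame(node = rep(seq_len(n), l), layer = rep(seq_len(l), each = n))
  .supra(tr$i, tr$j, tr$x, n * l, mu, layout, spec, "multiscale")
}

#' Assemble a two-modality multiplex supra-modularity structure
#'
#' Two gamma chains (one per modality, each with its own null model and
#' grid, internally coupled by `tau`) are joined by coefficients `kappa`
#' between the copies of each node at matching scale layers.
#'
#' @param spec a [multiplex_spec()].
#' @return a `supra_modularity` with `2 * N * L` node-layers (modality A
#'   occupies the first `N * L` flat indices).
#' @export
build_multiplex <- function(spec) {
  stopifnot(inherits(spec, "multiplex_spec"))
  n <- spec$graph_a$n_nodes
  l <- length(spec$gamma_grid_a)
  pa <- null_expected_matrix(spec$null_a, spec$graph_a)
  pb <- null_expected_matrix(spec$null_b, spec$graph_b)
  ta <- .chain_triplets(spec$graph_a$weights, pa, spec$gamma_grid_a, spec$tau, 0L)
  tb <- .chain_triplets(spec$graph_b$weights, pb, spec$gamma_grid_b, spec$tau, n * l)
  ii <- c(ta$i, tb$i); jj <- c(ta$j, tb$j); xx <- c(ta$x, tb$x)
  if (spec$kappa > 0) {
    idx <- seq_len(n * l)
    ii <- c(ii, idx)
    jj <- c(jj, idx + n * l)
    xx <- c(xx, rep(spec$kappa, n * l))
  }
  ma <- sum(spec$graph_a$weights) / 2
  mb <- sum(spec$graph_b$weights) / 2
  mu <- l * (ma + mb) + 2 * n * (l - 1L) * spec$tau + n * l * spec$kappa
  layout <- data.frame(node = rep(seq_len(n), 2L * l),
                       layer = rep(rep(seq_len(l), each = n), 2L),
                       modality = rep(1:2, each = n * l))
  .supra(ii, jj, xx, 2L * n * l, mu, layout, spec, "multiplex")
}

#' Assemble a multi-slice multi-scale supra-modularity structure
#'
#' Each slice's graph is swept through the shared gamma grid. Within a slice
#' and scale layer the coefficients are `A_l[i, j] - gamma_x * P_l[i, j]`;
#' copies of a node are coupled with `omega` across adjacent slices at the
#' same scale layer and with `tau` across adjacent scale layers within the
#' same slice. Strength bookkeeping adds both coupling families to `mu`.
#'
#' @param spec a [multislice_spec()].
#' @return a `supra_modularity` with `N * S * L` node-layers; flat index
#'   order is node fastest, then slice, then scale layer.
#' @export
build_multislice_multiscale <- function(spec) {
  stopifnot(inherits(spec, "multislice_spec"))
  n <- spec$slices[[1L]]$n_nodes
  s <- length(spec$slices)
  l <- length(spec$gamma_grid)
  flat <- function(node, slice, layer) ((layer - 1L) * s + (slice - 1L)) * n + node
  ii <- jj <- integer(0); xx <- numeric(0)
  for (sl in seq_len(s)) {
    w <- spec$slices[[sl]]$weights
    p <- null_expected_matrix(spec$nulls[[sl]], spec$slices[[sl]])
    up <- which(upper.tri(w))
    oi <- ((up - 1L) %% n) + 1L
    oj <- ((up - 1L) %/% n) + 1L
    wv <- w[up]; pv <- p[up]
    for (x in seq_len(l)) {
      vals <- wv - spec$gamma_grid[x] * pv
      ii <- c(ii, flat(oi, sl, x))
      jj <- c(jj, flat(oj, sl, x))
      xx <- c(xx, vals)
    }
  }
  nd <- seq_len(n)
  if (spec$omega > 0 && s > 1L) {
    for (x in seq_len(l)) for (sl in seq_len(s - 1L)) {
      ii <- c(ii, flat(nd, sl, x)); jj <- c(jj, flat(nd, sl + 1L, x))
      xx <- c(xx, rep(spec$omega, n))
    }
  }
  if (spec$tau > 0 && l > 1L) {
    for (x in seq_len(l - 1L)) for (sl in seq_len(s)) {
      ii <- c(ii, flat(nd, sl, x)); jj <- c(jj, flat(nd, sl, x + 1L))
      xx <- c(xx, rep(spec$tau, n))
    }
  }
  ms <- vapply(spec$slices, function(g) sum(g$weights) / 2, numeric(1L))
  mu <- l * sum(ms) + n * (s - 1L) * l * spec$omega + n * (l - 1L) * s * spec$tau
  layout <- data.frame(node = rep(nd, s * l),
                       slice = rep(rep(seq_len(s), each = n), l),
                       layer = rep(seq_len(l), each = n * s))
  .supra(ii, jj, xx, n * s * l, mu, layout, spec, "multislice_multiscale")
}

#' Serialize and restore a multi-scale spec as a JSON config block
#'
#' The block records the gamma grid as `{start, stop, step}`, the couplings,
#' and the null model (`kind` plus `mode` or `constant`); the graph itself is
#' referenced by the surrounding run configuration, not embedded.
#'
#' @param spec a [multiscale_spec()] (couplings `kappa`/`omega` from the
#'   multiplex/multi-slice variants can be carried via the optional fields).
#' @param gamma_start,gamma_stop,gamma_step grid parameters; inferred from
#'   the spec's grid when omitted.
#' @param kappa,omega optional extra couplings to record.
#' @return `spec_to_json`: a JSON string. `spec_from_json`: a list with
#'   elements `gamma_grid`, `tau`, `null`, and optional `kappa`, `omega`,
#'   ready to combine with a graph via [multiscale_spec()].
#' @export
spec_to_json <- function(spec, gamma_start = NULL, gamma_stop = NULL,
                         gamma_step = NULL, kappa = NULL, omega = NULL) {
  gg <- spec$gamma_grid
  step <- gamma_step %||% if (length(gg) > 1L) gg[2L] - gg[1L] else 1
  block <- list(
    gamma = list(start = gamma_start %||% gg[1L],
                 stop = gamma_stop %||% gg[length(gg)],
                 step = step),
    tau = spec$tau,
    null = c(list(kind = spec$null$kind),
             if (!is.null(spec$null$mode)) list(mode = spec$null$mode),
             if (!is.null(spec$null$constant)) list(constant = spec$null$constant))
  )
  if (!is.null(kappa)) block$kappa <- kappa
  if (!is.null(omega)) block$omega <- omega
  jsonlite::toJSON(block, auto_unbox = TRUE, digits = NA)
}

#' @rdname spec_to_json
#' @param json a JSON string or path produced by [spec_to_json()].
#' @export
spec_from_json <- function(json) {
  block <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  if (is.null(block$gamma) || is.null(block$tau) || is.null(block$null)) {
    stop("spec JSON must contain gamma, tau and null blocks")
  }
  out <- list(
    gamma_grid = make_gamma_grid(block$gamma$start, block$gamma$stop, block$gamma$step),
    tau = block$tau,
    null = null_model(block$null$kind,
                      constant = block$null$constant,
                      mode = block$null$mode)
  )
  if (!is.null(block$kappa)) out$kappa <- block$kappa
  if (!is.null(block$omega)) out$omega <- block$omega
  out
}
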