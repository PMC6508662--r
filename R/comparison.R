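#' Correlation map between two sets of allegiance matrices
#'
#' For every pair of layers (one from each input) the Pearson correlation
#' is computed between the upper-triangle entries of the two intra-layer
#' allegiance matrices (diagonals are constant 1 and are excluded). The map
#' localizes the topological scales at which two graphs -- for example a
#' structural and a functional network over the same nodes -- express
#' similar community structure, and its argmax identifies the best
#' alignment of their scale axes. Reading a diagonal of the map with an
#' offset corresponds to shifting one graph's layers against the other's.
#'
#' @param a,b `allegiance_set` objects over the same node set.
#' @return an object of class `correlation_map`: list with `values`
#'   (`L_a x L_b` matrix of correlations; `NA` where a layer has constant
#'   allegiance and the correlation is undefined), `best_alignment`
#'   (list `layer_a`, `layer_b`, `r`; the argmax over defined entries), and
#'   the two gamma grids.
#' @export
allegiance_correlation_map <- function(a, b) {
  stopifnot(inherits(a, "allegiance_set"), inherits(b, "allegiance_set"))
  n <- nrow(a$intra[[1L]])
  if (nrow(b$intra[[1L]]) != n) stop("allegiance sets must share the same node set")
  ut <- upper.tri(a$intra[[1L]])
  va <- vapply(a$intra, function(m) m[ut], numeric(sum(ut)))
  vb <- vapply(b$intra, function(m) m[ut], numeric(sum(ut)))
  la <- ncol(va); lb <- ncol(vb)
  vals <- matrix(NA_real_, la, lb)
  sda <- apply(va, 2L, stats::sd)
  sdb <- apply(vb, 2L, stats::sd)
  ok_a <- which(sda > 0); ok_b <- which(sdb > 0)
  if (length(ok_a) && length(ok_b)) {
    vals[ok_a, ok_b] <- stats::cor(va[, ok_a, drop = FALSE], vb[, ok_b, drop = FALSE])
  }
  best <- NULL
  if (any(is.finite(vals))) {
    idx <- which(vals == max(vals, na.rm = TRUE), arr.ind = TRUE)[1L, ]
    best <- list(layer_a = unname(idx[1L]), layer_b = unname(idx[2L]),
                 r = vals[idx[1L], idx[2L]])
  }
  structure(list(values = vals, best_alignment = best,
                 gamma_a = a$gamma_grid, gamma_b = b$gamma_grid),
            class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf("<correlation_map> %d x %d layers", nrow(x$values), ncol(x$values)))
  if (!is.null(x$best_alignment)) {
    cat(sprintf("; best r = %.3f at (%d, %d)", x$best_alignment$r,
                x$best_alignment$layer_a, x$best_alignment$layer_b))
  }
  cat("\n")
  invisible(x)
}

#' Correlation profile along a layer shift
#'
#' Extracts `map[x, x + shift]` for all valid `x`: the similarity obtained
#' when the second graph's layers are shifted against the first's.
#'
#' @param map a [allegiance_correlation_map()] result.
#' @param shift integer layer offset (may be negative).
#' @return numeric vector of correlations along the shifted diagonal.
#' @export
correlation_shift_profile <- function(map, shift = 0L) {
  stopifnot(inherits(map, "correlation_map"))
  la <- nrow(map$values); lb <- ncol(map$values)
  xs <- seq_len(la)
  ys <- xs + shift
  keep <- ys >= 1L & ys <= lb
  map$values[cbind(xs[keep], ys[keep])]
}

#' Spatially disconnected (multi-cluster) communities in one layer
#'
#' Counts the non-singleton communities of a layer's partition whose member
#' nodes fall into more than one connected component of a caller-supplied
#' spatial neighbor graph, and compares the count against a null obtained
#' by uniformly permuting the community labels over nodes. The one-sided
#' p-value is the fraction of null counts less than or equal to the
#' observed count -- small p means the observed communities are more
#' spatially contiguous than random label placement.
#'
#' @param layer_labels integer community label per node (one layer).
#' @param neighbor_graph a [weighted_graph()] whose positive entries define
#'   spatial adjacency over the same nodes.
#' @param n_permutations label permutations for the null (default 1000).
#' @param seed seed for the permutations.
#' @return list with `observed`, `null` (integer vector), and `p_value`.
#' @export
multi_cluster_count <- function(layer_labels, neighbor_graph,
                                n_permutations = 1000L, seed = 1L) {
  stopifnot(inherits(neighbor_graph, "weighted_graph"))
  labels <- as.integer(layer_labels)
  if (length(labels) != neighbor_graph$n_nodes) {
    stop("layer_labels and neighbor_graph must cover the same nodes")
  }
  ig <- igraph::graph_from_adjacency_matrix(neighbor_graph$weights > 0,
                                            mode = "undirected")
  count_disconnected <- function(lab) {
    out <- 0L
    for (cm in unique(lab)) {
      members <- which(lab == cm)
      if (length(members) < 2L) next
      sub <- igraph::induced_subgraph(ig, members)
      if (igraph::components(sub)$no > 1L) out <- out + 1L
    }
    out
  }
  observed <- count_disconnected(labels)
  set.seed(seed)
  null <- vapply(seq_len(n_permutations),
                 function(t) count_disconnected(sample(labels)), integer(1L))
  list(observed = observed, null = null, p_value = mean(null <= observed))
}

#' Pairwise node distances from multi-scale community assignments
#'
#' The distance between two nodes is the fraction of layers in which their
#' community labels differ (normalized Hamming distance over layers) -- a
#' metric in `[0, 1]`.
#'
#' @param p a `multiscale_partition`.
#' @param modality,slice which modality/slice to analyze.
#' @return a symmetric `N x N` distance matrix.
#' @export
community_label_distance <- function(p, modality = 1L, slice = 1L) {
  labs <- label_matrix(p, modality = modality, slice = slice)
  n <- nrow(labs); l <- ncol(labs)
  d <- matrix(0, n, n)
  for (x in seq_len(l)) {
    d <- d + outer(labs[, x], labs[, x], "!=")
  }
  d / l
}

#' Node ordering by similarity of multi-scale community assignments
#'
#' Sorts nodes so that rows/columns of an adjacency or allegiance matrix
#' can be displayed with multi-scale communities contiguous: average-linkage
#' hierarchical clustering on the normalized-Hamming label distances,
#' followed by optimal leaf ordering (the dendrogram's leaf sequence with
#' the minimum sum of successive distances over all flips of its internal
#' nodes).
#'
#' @param p a `multiscale_partition`.
#' @param modality,slice which modality/slice to analyze.
#' @return integer permutation of the nodes.
#' @export
leaf_order_nodes <- function(p, modality = 1L, slice = 1L) {
  d <- community_label_distance(p, modality = modality, slice = slice)
  n <- nrow(d)
  if (n <= 2L) return(seq_len(n))
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  .olo_order(hc, d)
}

# Optimal leaf ordering (dynamic program over the hclust tree): for every
# internal node, M[u, w] = minimum path cost of its leaf block with u
# leftmost and w rightmost; merging children L, R costs
# min_{m in L, k in R} M_L[u, m] + d[m, k] + M_R[k, w].
.olo_order <- function(hc, d) {
  n <- nrow(d)
  nodes <- vector("list", nrow(hc$merge))
  leaf_node <- function(i) {
    list(leaves = i, m = matrix(0, 1L, 1L, dimnames = list(i, i)),
         left = NULL, right = NULL, argm = NULL, argk = NULL)
  }
  get_node <- function(ref) if (ref < 0L) leaf_node(-ref) else nodes[[ref]]
  for (v in seq_len(nrow(hc$merge))) {
    lft <- get_node(hc$merge[v, 1L])
    rgt <- get_node(hc$merge[v, 2L])
    a <- lft$leaves; b <- rgt$leaves
    na <- length(a); nb <- length(b)
    dm <- d[a, b, drop = FALSE]
    m_v <- matrix(NA_real_, na, nb, dimnames = list(a, b))
    argm <- matrix(NA_integer_, na, nb)
    argk <- matrix(NA_integer_, na, nb)
    for (ui in seq_len(na)) {
      g <- lft$m[ui, ] + dm                 # na_m x nb over (m, k)
      if (is.null(dim(g))) g <- matrix(g, nrow = 1L)
      m_star <- apply(g, 2L, which.min)     # best m per k
      f <- g[cbind(m_star, seq_len(nb))]
      h <- f + rgt$m                        # nb x nb over (k, w)
      k_star <- apply(h, 2L, which.min)
      m_v[ui, ] <- h[cbind(k_star, seq_len(nb))]
      argk[ui, ] <- k_star
      argm[ui, ] <- m_star[k_star]
    }
    nodes[[v]] <- list(leaves = c(a, b), m_left = m_v,
                       left = lft, right = rgt, argm = argm, argk = argk)
    # full M over both orientations, for use as a child higher up
    full <- matrix(Inf, na + nb, na + nb,
                   dimnames = list(c(a, b), c(a, b)))
    full[seq_len(na), na + seq_len(nb)] <- m_v
    full[na + seq_len(nb), seq_len(na)] <- t(m_v)
    nodes[[v]]$m <- full
  }
  unwind <- function(node, u_lab, w_lab) {
    if (length(node$leaves) == 1L) return(node$leaves)
    a <- node$left$leaves; b <- node$right$leaves
    if (u_lab %in% a) {
      ui <- match(u_lab, a); wi <- match(w_lab, b)
      m_lab <- a[node$argm[ui, wi]]
      k_lab <- b[node$argk[ui, wi]]
      c(unwind(node$left, u_lab, m_lab), unwind(node$right, k_lab, w_lab))
    } else {
      ui <- match(w_lab, a); wi <- match(u_lab, b)
      m_lab <- a[node$argm[ui, wi]]
      k_lab <- b[node$argk[ui, wi]]
      c(unwind(node$right, u_lab, k_lab), unwind(node$left, m_lab, w_lab))
    }
  }
  root <- nodes[[nrow(hc$merge)]]
  best <- which(root$m_left == min(root$m_left), arr.ind = TRUE)[1L, ]
  u_lab <- root$left$leaves[best[1L]]
  w_lab <- root$right$leaves[best[2L]]
  ord <- unwind(root, u_lab, w_lab)
  stopifnot(length(ord) == n, !anyDuplicated(ord))
  ord
}
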