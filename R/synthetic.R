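#' Planted-hierarchy benchmark graph with nested weighted blocks
#'
#' Generates a weighted graph whose community structure is planted at
#' several nested topological scales: every node sits inside a small block,
#' which sits inside a medium block, which sits inside a large block (3 / 9
#' / 27 nodes by default, 81 nodes total). The edge weight between two
#' nodes is the base weight of the deepest block they share plus that
#' block's gradient offset; nodes sharing no block are connected at
#' `background_weight`. The gradient -- an additive ramp of
#' `gradient` per sibling block within its parent -- makes blocks of a given
#' size differ in average weight, planting topological heterogeneity:
#' under a uniform-null sweep, stronger blocks dissolve at proportionally
#' higher resolution values.
#'
#' The default weights place all four scale transitions of the hierarchy
#' (whole graph, large, medium, small blocks, then singletons) inside a
#' resolution sweep of `gamma in [0, 12]` when the uniform null constant is
#' the smallest positive weight: with constant `c`, a block whose internal
#' weight is `w` dissolves near `gamma = w / c`, giving transitions near
#' 1, ~3.x, ~7.x and ~11.x. Each level's weight band (base to base +
#' 2 * gradient) stays separated from its neighbors.
#'
#' The generator is deterministic given its specification; `seed` is only
#' used when `jitter_sd > 0` adds symmetric Gaussian noise to the weights.
#'
#' @param level_sizes increasing block sizes, innermost first; each must
#'   divide the next, and the largest must divide `n_nodes`.
#' @param n_nodes total number of nodes.
#' @param level_weights base within-block weight per level, innermost first,
#'   strictly decreasing.
#' @param gradient additive weight increment per sibling block (0-based
#'   sibling index within the parent block).
#' @param background_weight weight between nodes sharing no block; must stay
#'   below the outermost level weight.
#' @param jitter_sd standard deviation of optional weight noise.
#' @param seed seed for the jitter.
#' @return list with `graph` (a [weighted_graph()]) and `labels` (an
#'   `n_nodes x n_levels` matrix of planted block ids, innermost level
#'   first; perfectly nested).
#' @export
nested_benchmark <- function(level_sizes = c(3L, 9L, 27L),
                             n_nodes = 81L,
                             level_weights = c(0.551, 0.351, 0.151),
                             gradient = 0.02,
                             background_weight = 0.05,
                             jitter_sd = 0,
                             seed = 1L) {
  nl <- length(level_sizes)
  if (nl < 1L || length(level_weights) != nl) {
    stop("need one level weight per level size")
  }
  if (any(diff(level_sizes) <= 0)) stop("level_sizes must be increasing")
  for (k in seq_len(nl - 1L)) {
    if (level_sizes[k + 1L] %% level_sizes[k] != 0L) {
      stop("each level size must divide the next (nested blocks)")
    }
  }
  if (n_nodes %% level_sizes[nl] != 0L) {
    stop("n_nodes must be a multiple of the largest block size")
  }
  if (any(diff(level_weights) >= 0)) {
    stop("level_weights must strictly decrease outward")
  }
  if (any(level_weights < 0) || background_weight < 0 || gradient < 0) {
    stop("weights must be nonnegative")
  }
  if (background_weight >= level_weights[nl]) {
    stop("background_weight must be below the outermost level weight")
  }

  blocks <- vapply(level_sizes, function(sz) (seq_len(n_nodes) - 1L) %/% sz + 1L,
                   integer(n_nodes))
  colnames(blocks) <- paste0("level_", seq_len(nl))
  parent_sizes <- c(level_sizes[-1L], n_nodes)
  w <- matrix(background_weight, n_nodes, n_nodes)
  # paint from outermost level inward so deeper shared blocks overwrite
  for (lev in rev(seq_len(nl))) {
    sz <- level_sizes[lev]
    per_parent <- parent_sizes[lev] %/% sz
    for (b in seq_len(n_nodes %/% sz)) {
      members <- which(blocks[, lev] == b)
      sib <- (b - 1L) %% per_parent
      w[members, members] <- level_weights[lev] + gradient * sib
    }
  }
  diag(w) <- 0
  if (jitter_sd > 0) {
    set.seed(seed)
    noise <- matrix(stats::rnorm(n_nodes^2, sd = jitter_sd), n_nodes, n_nodes)
    noise <- (noise + t(noise)) / 2
    w <- pmax(w + noise, 0)
    diag(w) <- 0
  }
  list(graph = weighted_graph(w), labels = blocks)
}

#' Strength-preserving rewired null graph
#'
#' Destroys planted community structure while matching the original graph's
#' gross weight statistics: the binary topology is randomized by seeded
#' double-edge swaps (degree sequence preserved exactly), after which the
#' original weight multiset is reassigned to the new edges -- a seeded
#' random permutation followed by greedy pairwise weight swaps that
#' monotonically reduce the squared error against the original strength
#' sequence. Weight multiset and degree sequence are preserved exactly;
#' the strength sequence approximately (its agreement is a measured
#' property, reported by the tests, not an assumption).
#'
#' @param g a [weighted_graph()] with at least 2 edges and 4 nodes.
#' @param n_swaps attempted double-edge swaps for the topology
#'   (default `10 *` edge count).
#' @param n_weight_swaps attempted weight swaps in the strength-matching
#'   stage (default `20 *` edge count).
#' @param seed integer seed.
#' @return a `weighted_graph` of the same size.
#' @export
rewire_null <- function(g, n_swaps = NULL, n_weight_swaps = NULL, seed = 1L) {
  stopifnot(inherits(g, "weighted_graph"))
  n <- g$n_nodes
  up <- which(upper.tri(g$weights) & g$weights > 0)
  ne <- length(up)
  if (n < 4L || ne < 2L) stop("graph too small to rewire (need >= 4 nodes and >= 2 edges)")
  if (is.null(n_swaps)) n_swaps <- 10L * ne
  if (is.null(n_weight_swaps)) n_weight_swaps <- 20L * ne
  weights_multiset <- g$weights[up]
  s_target <- rowSums(g$weights)

  set.seed(seed)
  ig <- igraph::graph_from_adjacency_matrix(g$weights > 0, mode = "undirected")
  ig <- igraph::rewire(ig, igraph::keeping_degseq(loops = FALSE, niter = n_swaps))
  el <- igraph::as_edgelist(ig, names = FALSE)
  ea <- pmin(el[, 1L], el[, 2L])
  eb <- pmax(el[, 1L], el[, 2L])

  wv <- sample(weights_multiset) # random initial assignment
  s_cur <- numeric(n)
  for (e in seq_len(ne)) {
    s_cur[ea[e]] <- s_cur[ea[e]] + wv[e]
    s_cur[eb[e]] <- s_cur[eb[e]] + wv[e]
  }
  pick1 <- sample.int(ne, n_weight_swaps, replace = TRUE)
  pick2 <- sample.int(ne, n_weight_swaps, replace = TRUE)
  for (t in seq_len(n_weight_swaps)) {
    e1 <- pick1[t]; e2 <- pick2[t]
    if (e1 == e2 || wv[e1] == wv[e2]) next
    d <- wv[e2] - wv[e1]
    nodes4 <- c(ea[e1], eb[e1], ea[e2], eb[e2])
    delta4 <- c(d, d, -d, -d)
    un <- unique(nodes4)
    net <- vapply(un, function(v) sum(delta4[nodes4 == v]), numeric(1L))
    old_err <- sum((s_cur[un] - s_target[un])^2)
    new_err <- sum((s_cur[un] + net - s_target[un])^2)
    if (new_err < old_err) {
      tmp <- wv[e1]; wv[e1] <- wv[e2]; wv[e2] <- tmp
      s_cur[un] <- s_cur[un] + net
    }
  }
  w_null <- matrix(0, n, n)
  w_null[cbind(ea, eb)] <- wv
  w_null[cbind(eb, ea)] <- wv
  weighted_graph(w_null, node_labels = g$node_labels)
}

#' Two-timescale dynamic benchmark of graph slices
#'
#' Generates an ordered sequence of graph slices whose community structure
#' switches at two nested timescales: within a slow epoch the structure
#' alternates among `fast_states` planted partitions every
#' `periods[1]` slices, and the active set of partitions itself rotates
#' among `slow_states` sets every `periods[2]` slices. Detecting
#' communities on the resulting multi-slice problem at a low inter-slice
#' coupling recovers the fast switching; a high coupling merges slices into
#' the slow-scale structure.
#'
#' @param n_nodes number of nodes per slice.
#' @param fast_states partitions alternating at the fast timescale.
#' @param slow_states sets of partitions rotating at the slow timescale.
#' @param periods integer vector `c(fast, slow)`; `slow` must be a multiple
#'   of `fast`.
#' @param n_communities communities per planted partition.
#' @param n_slices total slices (default one full rotation:
#'   `slow_states * periods[2]`).
#' @param within_weight,between_weight edge weights inside / across the
#'   active partition's communities.
#' @param seed seed for the planted partitions.
#' @return list with `slices` (list of [weighted_graph()]), `structure_id`
#'   (planted structure index per slice), and `structure_labels`
#'   (`n_nodes x n_structures` matrix of planted community labels).
#' @export
dynamic_benchmark <- function(n_nodes, fast_states = 2L, slow_states = 2L,
                              periods = c(2L, 8L), n_communities = 3L,
                              n_slices = NULL,
                              within_weight = 1, between_weight = 0.1,
                              seed = 1L) {
  fast <- periods[1L]; slow <- periods[2L]
  if (slow %% fast != 0L) stop("slow period must be a multiple of the fast period")
  if (is.null(n_slices)) n_slices <- slow_states * slow
  n_struct <- fast_states * slow_states
  set.seed(seed)
  structure_labels <- vapply(seq_len(n_struct), function(m) {
    sample(rep(seq_len(n_communities), length.out = n_nodes))
  }, integer(n_nodes))
  graphs <- lapply(seq_len(n_struct), function(m) {
    lab <- structure_labels[, m]
    w <- matrix(between_weight, n_nodes, n_nodes)
    same <- outer(lab, lab, "==")
    w[same] <- within_weight
    diag(w) <- 0
    weighted_graph(w)
  })
  t_idx <- seq_len(n_slices) - 1L
  slow_epoch <- (t_idx %/% slow) %% slow_states
  fast_phase <- (t_idx %/% fast) %% fast_states
  structure_id <- slow_epoch * fast_states + fast_phase + 1L
  list(slices = graphs[structure_id],
       structure_id = structure_id,
       structure_labels = structure_labels)
}
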