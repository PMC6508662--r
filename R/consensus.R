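#' Configuration for consensus clustering of a partition ensemble
#'
#' @param n_runs ensemble size used upstream (recorded for provenance).
#' @param n_permutations label-permutation replicates for the null
#'   distributions (>= 100; 1000 by default).
#' @param alpha significance level in `(0, 1)`.
#' @param correction multiple-comparison correction over tested allegiance
#'   entries: `"bonferroni"` (default) or `"none"`.
#' @param consensus_gamma resolution parameter for partitioning the
#'   consensus multilayer graph (default 1).
#' @param consensus_omega scale applied to the significant inter-layer
#'   allegiance couplings of the consensus graph (default 1).
#' @param seed seed for the permutation draws and the consensus
#'   optimization.
#' @return an object of class `consensus_config`.
#' @export
consensus_config <- function(n_runs = 100L, n_permutations = 1000L,
                             alpha = 0.05,
                             correction = c("bonferroni", "none"),
                             consensus_gamma = 1, consensus_omega = 1,
                             seed = 1L) {
  correction <- match.arg(correction)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_permutations < 100L) stop("n_permutations must be >= 100")
  structure(list(n_runs = as.integer(n_runs),
                 n_permutations = as.integer(n_permutations),
                 alpha = alpha, correction = correction,
                 consensus_gamma = consensus_gamma,
                 consensus_omega = consensus_omega,
                 seed = as.integer(seed)),
            class = "consensus_config")
}

#' Permutation null distributions for allegiance values
#'
#' The null randomly permutes the node-to-label assignment within every
#' (run, layer) of the ensemble -- preserving each layer's community-size
#' histogram -- and recomputes allegiance. Under such a permutation every
#' off-diagonal intra-layer entry is exchangeable, so the permutation
#' distribution of any single entry is obtained exactly by drawing, per
#' replicate and run, a uniformly random pair of distinct node positions
#' and averaging the label matches across runs; the same argument gives the
#' inter-layer (persistence) null from two independent uniform positions.
#' This is what the function does, making 1000 replicates tractable even
#' for hundreds of layers.
#'
#' @param e a `partition_ensemble`.
#' @param cfg a [consensus_config()] (supplies `n_permutations` and `seed`).
#' @param modality,slice which modality/slice to analyze.
#' @return list with `intra` (list over layers of numeric vectors of length
#'   `n_permutations`) and `inter` (list over layer pairs, same shape).
#' @export
allegiance_null <- function(e, cfg = consensus_config(), modality = 1L, slice = 1L) {
  stopifnot(inherits(e, "partition_ensemble"), inherits(cfg, "consensus_config"))
  mats <- lapply(e$runs, label_matrix, modality = modality, slice = slice)
  n <- nrow(mats[[1L]])
  l <- ncol(mats[[1L]])
  r <- length(mats)
  np <- cfg$n_permutations
  set.seed(cfg$seed)
  intra <- vector("list", l)
  for (x in seq_len(l)) {
    labs <- vapply(mats, function(m) m[, x], integer(n)) # n x r
    a <- matrix(sample.int(n, np * r, replace = TRUE), np, r)
    bshift <- matrix(sample.int(n - 1L, np * r, replace = TRUE), np, r)
    bpos <- ((a + bshift - 1L) %% n) + 1L  # uniform over positions != a
    eq <- matrix(labs[cbind(as.vector(a), rep(seq_len(r), each = np))] ==
                 labs[cbind(as.vector(bpos), rep(seq_len(r), each = np))], np, r)
    intra[[x]] <- rowMeans(eq)
  }
  inter <- vector("list", max(l - 1L, 0L))
  if (l > 1L) {
    for (x in seq_len(l - 1L)) {
      labs1 <- vapply(mats, function(m) m[, x], integer(n))
      labs2 <- vapply(mats, function(m) m[, x + 1L], integer(n))
      a <- matrix(sample.int(n, np * r, replace = TRUE), np, r)
      b <- matrix(sample.int(n, np * r, replace = TRUE), np, r)
      eq <- matrix(labs1[cbind(as.vector(a), rep(seq_len(r), each = np))] ==
                   labs2[cbind(as.vector(b), rep(seq_len(r), each = np))], np, r)
      inter[[x]] <- rowMeans(eq)
    }
  }
  list(intra = intra, inter = inter)
}

# (1 - alpha[/n_tests]) empirical quantile of a null sample
.null_threshold <- function(null_draws, alpha, correction, n_tests) {
  a <- if (correction == "bonferroni") alpha / n_tests else alpha
  a <- max(a, .Machine$double.eps)
  stats::quantile(null_draws, probs = min(1 - a, 1), names = FALSE, type = 1L)
}

#' Consensus partition of a partition ensemble
#'
#' Implements the allegiance-based consensus pipeline: (i) the ensemble of
#' optimizations is summarized by (ii) intra-layer and (iii) inter-layer
#' allegiance, (iv) each entry is compared against its label-permutation
#' null, (v) entries not exceeding the null threshold are removed and the
#' significant entries keep their average-allegiance weight, forming a
#' consensus multilayer graph, and (vi) that graph is partitioned by the
#' generalized Louvain optimizer at `consensus_gamma` (Newman-Girvan null
#' per layer) with the significant inter-layer allegiance (scaled by
#' `consensus_omega`) as couplings.
#'
#' Layers whose labeling is constant in every run (a single community, or
#' all singletons) are their own permutation null, so no entry of theirs is
#' significant and they resolve to isolated singletons in the consensus
#' graph -- the honest statistical answer for degenerate layers.
#'
#' @param e a `partition_ensemble` of at least 2 runs.
#' @param cfg a [consensus_config()].
#' @param modality,slice which modality/slice to analyze.
#' @return an object of class `consensus_result`: list with `partition`
#'   (a `multiscale_partition` of the consensus graph), `intra_significant`
#'   (list of thresholded allegiance matrices), `inter_significant`
#'   (`N x (L-1)` matrix), `reliability` (see
#'   [interlayer_reliability()]), and `config`.
#' @export
consensus_partition <- function(e, cfg = consensus_config(), modality = 1L, slice = 1L) {
  stopifnot(inherits(e, "partition_ensemble"), inherits(cfg, "consensus_config"))
  if (length(e$runs) < 2L) {
    stop("consensus needs an ensemble of at least 2 runs (allegiance degenerate)")
  }
  al <- allegiance(e, modality = modality, slice = slice)
  nulls <- allegiance_null(e, cfg, modality = modality, slice = slice)
  n <- nrow(al$intra[[1L]])
  l <- length(al$intra)
  n_tests <- l * n * (n - 1L) / 2 + max(l - 1L, 0L) * n

  intra_sig <- vector("list", l)
  for (x in seq_len(l)) {
    thr <- .null_threshold(nulls$intra[[x]], cfg$alpha, cfg$correction, n_tests)
    m <- al$intra[[x]]
    m[m <= thr] <- 0
    diag(m) <- 0
    intra_sig[[x]] <- m
  }
  inter_sig <- matrix(0, n, max(l - 1L, 0L))
  if (l > 1L) {
    for (x in seq_len(l - 1L)) {
      thr <- .null_threshold(nulls$inter[[x]], cfg$alpha, cfg$correction, n_tests)
      v <- al$inter[, x]
      v[v <= thr] <- 0
      inter_sig[, x] <- v
    }
  }

  b <- .consensus_supra(intra_sig, inter_sig, cfg$consensus_gamma,
                        cfg$consensus_omega, gamma_grid = e$gamma_grid)
  part <- louvain_optimize(b, seed = cfg$seed)
  rel <- if (l >= 2L) {
    interlayer_reliability(e, cfg, nulls = nulls,
                           modality = modality, slice = slice)
  } else NULL
  structure(list(partition = part,
                 intra_significant = intra_sig,
                 inter_significant = inter_sig,
                 reliability = rel,
                 config = cfg),
            class = "consensus_result")
}

# supra structure of the thresholded-allegiance multilayer graph:
# per-layer Newman-Girvan null at `gamma`, couplings = omega * inter weights
.consensus_supra <- function(intra_sig, inter_sig, gamma, omega,
                             gamma_grid = NULL) {
  n <- nrow(intra_sig[[1L]])
  l <- length(intra_sig)
  ii <- jj <- integer(0); xx <- numeric(0)
  up <- which(upper.tri(intra_sig[[1L]]))
  oi <- ((up - 1L) %% n) + 1L
  oj <- ((up - 1L) %/% n) + 1L
  mu <- 0
  for (x in seq_len(l)) {
    w <- intra_sig[[x]]
    two_m <- sum(w)
    mu <- mu + two_m / 2
    if (two_m > 0) {
      k <- rowSums(w)
      vals <- w[up] - gamma * (k[oi] * k[oj]) / two_m
      base <- (x - 1L) * n
      ii <- c(ii, base + oi)
      jj <- c(jj, base + oj)
      xx <- c(xx, vals)
    }
  }
  if (l > 1L && omega > 0) {
    for (x in seq_len(l - 1L)) {
      cw <- omega * inter_sig[, x]
      nz <- which(cw > 0)
      if (length(nz)) {
        ii <- c(ii, (x - 1L) * n + nz)
        jj <- c(jj, x * n + nz)
        xx <- c(xx, cw[nz])
        mu <- mu + sum(cw[nz])
      }
    }
  }
  if (mu <= 0) mu <- 1 # fully empty consensus graph; scale is irrelevant
  layout <- data.frame(node = rep(seq_len(n), l), layer = rep(seq_len(l), each = n))
  # carry the source grid so layer <-> gamma bookkeeping survives consensus
  spec <- list(gamma_grid = gamma_grid %||% seq_len(l))
  .supra(ii, jj, xx, n * l, mu, layout, spec, "consensus")
}

#' Inter-layer reliability of node community allegiance
#'
#' A node's inter-layer edge between layers `x` and `x + 1` is reliable when
#' the fraction of optimizations in which the node keeps its community
#' across the two layers exceeds the label-permutation null at level
#' `alpha`. Summaries: the per-node ratio of reliable edges to the `L - 1`
#' possible ones, and the percentage of nodes with a reliable edge at each
#' layer transition.
#'
#' @param e a `partition_ensemble` over at least 2 layers.
#' @param cfg a [consensus_config()]; its `alpha` is applied per edge with
#'   the chosen `correction`.
#' @param nulls optional precomputed [allegiance_null()] output.
#' @param correction override for the multiple-comparison correction
#'   (`"none"` by default here: reliability maps are descriptive, per-edge).
#' @param modality,slice which modality/slice to analyze.
#' @return list with `reliable` (logical `N x (L-1)` matrix), `ratio`
#'   (per-node fraction of reliable inter-layer edges), and
#'   `pct_nodes_reliable` (per layer-pair percentage of nodes).
#' @export
interlayer_reliability <- function(e, cfg = consensus_config(), nulls = NULL,
                                   correction = "none",
                                   modality = 1L, slice = 1L) {
  stopifnot(inherits(e, "partition_ensemble"))
  if (e$n_layers < 2L) stop("inter-layer reliability needs at least 2 layers")
  al <- allegiance(e, modality = modality, slice = slice)
  if (is.null(nulls)) nulls <- allegiance_null(e, cfg, modality = modality, slice = slice)
  n <- nrow(al$inter)
  lp <- ncol(al$inter)
  n_tests <- lp * n
  reliable <- matrix(FALSE, n, lp)
  for (x in seq_len(lp)) {
    thr <- .null_threshold(nulls$inter[[x]], cfg$alpha, correction, n_tests)
    reliable[, x] <- al$inter[, x] > thr
  }
  list(reliable = reliable,
       ratio = rowMeans(reliable),
       pct_nodes_reliable = colMeans(reliable) * 100)
}
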