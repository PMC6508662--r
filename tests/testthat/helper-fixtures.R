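# Shared fixtures, all built in code.

# two disjoint k-cliques with unit weights
two_cliques_graph <- function(k = 3L) {
  n <- 2L * k
  w <- matrix(0, n, n)
  w[seq_len(k), seq_len(k)] <- 1
  w[k + seq_len(k), k + seq_len(k)] <- 1
  diag(w) <- 0
  weighted_graph(w)
}

two_cliques_labels <- function(k = 3L) rep(1:2, each = k)

# seeded random symmetric weight matrix with zero diagonal
random_graph <- function(n, seed, density = 1, wmax = 1) {
  set.seed(seed)
  w <- matrix(stats::runif(n * n, 0, wmax), n, n)
  if (density < 1) {
    mask <- matrix(stats::runif(n * n) < density, n, n)
    w <- w * mask
  }
  w <- (w + t(w)) / 2
  diag(w) <- 0
  weighted_graph(w)
}

# small nested benchmark for fast structural tests: 27 nodes, triads in
# 9-blocks in one 27-block is degenerate, so use levels (3, 9) over 27
small_benchmark <- function() {
  nested_benchmark(level_sizes = c(3L, 9L), n_nodes = 27L,
                   level_weights = c(0.551, 0.351),
                   gradient = 0.02, background_weight = 0.05)
}

# a reference multi-scale partition of the small benchmark (single run)
small_benchmark_partition <- function(gamma_stop = 12, step = 0.25, tau = 0.05,
                                      seed = 5L) {
  bench <- small_benchmark()
  grid <- make_gamma_grid(0, gamma_stop, step)
  spec <- multiscale_spec(bench$graph, grid, tau = tau,
                          null = null_model("uniform", mode = "min_positive"))
  b <- build_multiscale(spec)
  list(bench = bench, supra = b, partition = louvain_optimize(b, seed = seed))
}

ring_lattice_graph <- function(n) {
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i %% n) + 1L
    w[i, j] <- 1; w[j, i] <- 1
  }
  weighted_graph(w)
}

path_graph <- function(n) {
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    w[i, i + 1L] <- 1; w[i + 1L, i] <- 1
  }
  weighted_graph(w)
}
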