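test_that("gamma grids reproduce documented layer counts", {
  expect_length(make_gamma_grid(0, 12, 0.05), 241L)
  expect_length(make_gamma_grid(0.0133, 1, 0.0133), 75L)
  expect_equal(make_gamma_grid(1, 1, 0.1), 1)
  g <- make_gamma_grid(0.95, 1.7, 0.01)
  expect_length(g, 76L)  # inclusive endpoint rule
  expect_true(all(diff(g) > 0))
  expect_error(make_gamma_grid(0, 1, 0), "positive")
  expect_error(make_gamma_grid(0, 1, -0.1), "positive")
  expect_error(make_gamma_grid(2, 1, 0.1), "start")
})

test_that("spec constructors validate their invariants", {
  g <- two_cliques_graph()
  nm <- null_model("uniform", constant = 0.5)
  expect_error(multiscale_spec(g, c(1, 1), 0.1, nm), "strictly increasing")
  expect_error(multiscale_spec(g, c(1, 2), -0.1, nm), "nonnegative")
  expect_error(multiplex_spec(g, two_cliques_graph(4), 1, 1, 0.1, 0.1, nm, nm),
               "same node set")
  expect_error(multiplex_spec(g, g, c(1, 2), 1, 0.1, 0.1, nm, nm),
               "equal length")
  expect_error(multislice_spec(list(g, two_cliques_graph(4)), 1, 0.1, 0.1, nm),
               "same node set")
})

test_that("a single-layer chain equals the single-scale coefficients", {
  g <- two_cliques_graph()
  nm <- null_model("newman_girvan")
  b <- build_multiscale(multiscale_spec(g, 1.5, tau = 0.3, null = nm))
  p <- null_expected_matrix(nm, g)
  expected <- g$weights - 1.5 * p
  diag(expected) <- 0
  expect_equal(as.matrix(b$matrix), expected, ignore_attr = TRUE)
  expect_equal(b$mu, sum(g$weights) / 2)
})

test_that("the worked 2-node, 2-layer chain matches hand-computed values", {
  # single edge of weight 1, uniform constant 0.5, grid {1, 2}, tau 0.3
  g <- weighted_graph(matrix(c(0, 1, 1, 0), 2, 2))
  spec <- multiscale_spec(g, c(1, 2), tau = 0.3,
                          null = null_model("uniform", constant = 0.5))
  b <- build_multiscale(spec)
  expect_equal(b$n_node_layers, 4L)
  # layer 1: A - 1 * 0.5 = 0.5; layer 2: A - 2 * 0.5 = 0
  expect_equal(supra_coef(b, 1, 1, 2, 1), 0.5)
  expect_equal(supra_coef(b, 1, 2, 2, 2), 0)
  # adjacent-layer self couplings
  expect_equal(supra_coef(b, 1, 1, 1, 2), 0.3)
  expect_equal(supra_coef(b, 2, 1, 2, 2), 0.3)
  # cross terms that must be zero
  expect_equal(supra_coef(b, 1, 1, 2, 2), 0)
  expect_equal(supra_coef(b, 2, 1, 1, 2), 0)
  # mu: k = 1 per node-layer (sum 4), coupling strength 0.3 per node-layer
  # (sum 1.2) -> mu = (4 + 1.2) / 2 = 2.6
  expect_equal(b$mu, 2.6)
})

test_that("tau = 0 gives a block-diagonal structure over layers", {
  g <- two_cliques_graph()
  spec <- multiscale_spec(g, c(1, 2, 3), tau = 0,
                          null = null_model("uniform", constant = 0.5))
  b <- build_multiscale(spec)
  n <- g$n_nodes
  bd <- as.matrix(b$matrix)
  for (x in 1:3) for (y in 1:3) {
    if (x == y) next
    blk <- bd[(x - 1) * n + seq_len(n), (y - 1) * n + seq_len(n)]
    expect_true(all(blk == 0))
  }
})

test_that("coupling is adjacent-only along the chain", {
  g <- two_cliques_graph()
  spec <- multiscale_spec(g, c(1, 2, 3, 4), tau = 0.2,
                          null = null_model("uniform", constant = 0.5))
  b <- build_multiscale(spec)
  expect_equal(supra_coef(b, 1, 1, 1, 2), 0.2)
  expect_equal(supra_coef(b, 1, 2, 1, 3), 0.2)
  expect_equal(supra_coef(b, 1, 1, 1, 3), 0)  # not adjacent
  expect_equal(supra_coef(b, 1, 1, 1, 4), 0)
})

test_that("supra coefficient sums match independent summation", {
  g <- random_graph(5, seed = 7)
  nm <- null_model("uniform", constant = 0.2)
  grid <- c(0.5, 1, 1.5)
  tau <- 0.15
  b <- build_multiscale(multiscale_spec(g, grid, tau, nm))
  p <- null_expected_matrix(nm, g)
  off <- row(p) != col(p)
  expected_sum <- sum(vapply(grid, function(gam) sum((g$weights - gam * p)[off]),
                             numeric(1))) +
    2 * g$n_nodes * (length(grid) - 1) * tau
  expect_equal(sum(b$matrix), expected_sum)
  # symmetry is exact
  expect_equal(max(abs(b$matrix - Matrix::t(b$matrix))), 0)
  expect_gt(b$mu, 0)
})

test_that("multiplex structures couple modalities at matching layers", {
  g <- two_cliques_graph(2)  # 4 nodes
  nm <- null_model("uniform", constant = 0.5)
  spec <- multiplex_spec(g, g, c(1, 2), c(1, 2), tau = 0.1, kappa = 0.4,
                         null_a = nm, null_b = nm)
  b <- build_multiplex(spec)
  n <- 4L; l <- 2L
  expect_equal(b$n_node_layers, 2L * n * l)
  # kappa appears exactly once per (node, layer) pair across modalities
  for (i in 1:2) for (x in 1:2) {
    expect_equal(supra_coef(b, i, x, i, x, modality_i = 1, modality_j = 2), 0.4)
  }
  expect_equal(supra_coef(b, 1, 1, 1, 2, modality_i = 1, modality_j = 2), 0)
  expect_equal(supra_coef(b, 1, 1, 2, 1, modality_i = 1, modality_j = 2), 0)
  # count the kappa couplings in the full matrix: N*L symmetric pairs
  bd <- as.matrix(b$matrix)
  cross <- bd[seq_len(n * l), n * l + seq_len(n * l)]
  expect_equal(sum(cross == 0.4), n * l)

  # N = 3-node toy from a labeled triangle: 12 node-layers and 6 couplings
  w3 <- matrix(0.2, 3, 3); diag(w3) <- 0
  g3 <- weighted_graph(w3)
  b3 <- build_multiplex(multiplex_spec(g3, g3, c(1, 2), c(1, 2), 0.1, 0.4, nm, nm))
  expect_equal(b3$n_node_layers, 12L)
  bd3 <- as.matrix(b3$matrix)
  expect_equal(sum(bd3[seq_len(6), 6 + seq_len(6)] == 0.4), 6)
})

test_that("one slice reduces the multi-slice builder to the scale chain", {
  g <- two_cliques_graph()
  nm <- null_model("uniform", constant = 0.5)
  grid <- c(1, 2, 3)
  b_ms <- build_multislice_multiscale(multislice_spec(list(g), grid, tau = 0.2,
                                                      omega = 0.7, nulls = nm))
  b_chain <- build_multiscale(multiscale_spec(g, grid, tau = 0.2, null = nm))
  expect_equal(as.matrix(b_ms$matrix), as.matrix(b_chain$matrix),
               ignore_attr = TRUE)
  expect_equal(b_ms$mu, b_chain$mu)
})

test_that("omega = 0 decouples slices into independent chains", {
  g1 <- two_cliques_graph(2)
  g2 <- random_graph(4, seed = 9)
  nm <- null_model("uniform", constant = 0.3)
  b <- build_multislice_multiscale(multislice_spec(list(g1, g2), c(1, 2),
                                                   tau = 0.1, omega = 0,
                                                   nulls = nm))
  # no coefficient joins different slices
  lay <- b$layout
  bd <- as.matrix(b$matrix)
  for (p in seq_len(nrow(lay))) for (q in seq_len(nrow(lay))) {
    if (lay$slice[p] != lay$slice[q]) expect_equal(bd[p, q], 0)
  }
})

test_that("the 2x2x2 multi-slice toy matches direct evaluation of the terms", {
  w1 <- matrix(c(0, 1, 1, 0), 2, 2)
  w2 <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  g1 <- weighted_graph(w1); g2 <- weighted_graph(w2)
  nm <- null_model("uniform", constant = 0.25)
  grid <- c(1, 2); tau <- 0.1; omega <- 0.3
  spec <- multislice_spec(list(g1, g2), grid, tau = tau, omega = omega, nulls = nm)
  b <- build_multislice_multiscale(spec)
  ws <- list(w1, w2)
  for (i in 1:2) for (j in 1:2) for (sl in 1:2) for (x in 1:2) {
    for (sj in 1:2) for (y in 1:2) {
      expected <-
        if (sl == sj && x == y && i != j) ws[[sl]][i, j] - grid[x] * 0.25
        else if (i == j && x == y && abs(sl - sj) == 1) omega
        else if (i == j && sl == sj && abs(x - y) == 1) tau
        else 0
      expect_equal(supra_coef(b, i, x, j, y, slice_i = sl, slice_j = sj),
                   expected)
    }
  }
  # mu = L*sum(m_l) + N(S-1)L*omega + N(L-1)S*tau
  expect_equal(b$mu, 2 * (1 + 0.5) + 2 * 1 * 2 * omega + 2 * 1 * 2 * tau)
})

test_that("spec JSON blocks round-trip", {
  g <- two_cliques_graph()
  spec <- multiscale_spec(g, make_gamma_grid(0, 2, 0.5), tau = 0.4,
                          null = null_model("uniform", mode = "min_positive"))
  js <- spec_to_json(spec, kappa = 0.7)
  back <- spec_from_json(js)
  expect_equal(back$gamma_grid, spec$gamma_grid)
  expect_equal(back$tau, 0.4)
  expect_equal(back$null$kind, "uniform")
  expect_equal(back$null$mode, "min_positive")
  expect_equal(back$kappa, 0.7)
  expect_error(spec_from_json('{"tau": 1}'), "must contain")
})
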