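# a hand-built partition over a known label matrix, for definition checks
partition_from_labels <- function(labs) {
  n <- nrow(labs); l <- ncol(labs)
  g <- weighted_graph(matrix(0.5, n, n) - diag(0.5, n))
  b <- build_multiscale(multiscale_spec(g, seq_len(l), tau = 0.01,
                                        null = null_model("uniform", constant = 0.1)))
  multiscale_partition(as.vector(labs), b)
}

test_that("stability values follow the layer-count definition", {
  labs <- rbind(c(1, 1, 1, 1),    # one community across all layers
                c(1, 1, 2, 2),    # half/half
                c(3, 4, 5, 6))    # different community at every layer
  p <- partition_from_labels(labs)
  s <- stability_matrix(p)
  expect_equal(s$values[1, ], rep(1, 4))
  expect_equal(s$values[2, ], rep(0.5, 4))
  expect_equal(s$values[3, ], rep(0.25, 4))
  expect_true(all(s$values >= 0 & s$values <= 1))
  expect_true(all(s$values %in% ((1:4) / 4)))
})

test_that("distinct-community spans partition the layer set", {
  res <- small_benchmark_partition()
  s <- stability_matrix(res$partition)
  spans <- node_community_spans(s)
  l <- s$n_layers
  for (sp in spans) expect_equal(sum(sp), l)
  # equivalently the per-node stability summed once per community is 1
  for (i in seq_len(nrow(s$values))) {
    first <- !duplicated(s$labels[i, ])
    expect_equal(sum(s$values[i, first]), 1)
  }
})

test_that("stable-community counts follow the threshold definition", {
  # spans of 50% / 30% / 20% of layers; threshold 25 keeps two of them
  labs <- matrix(rep(c(rep(1, 5), rep(2, 3), rep(3, 2)), 2), nrow = 2,
                 byrow = TRUE)
  p <- partition_from_labels(rbind(labs[1, ], labs[1, ]))
  s <- stability_matrix(p)
  expect_equal(count_stable_communities(s, 25)[1], 2L)
  expect_equal(count_stable_communities(s, 0)[1], 3L)
  expect_equal(count_stable_communities(s, 45)[1], 1L)
  expect_equal(count_stable_communities(s, 50)[1], 0L)  # strictly greater than
})

test_that("stable-community counts are non-increasing in the threshold", {
  res <- small_benchmark_partition()
  s <- stability_matrix(res$partition)
  prev <- count_stable_communities(s, 0)
  for (thr in seq(5, 100, by = 5)) {
    cur <- count_stable_communities(s, thr)
    expect_true(all(cur <= prev))
    prev <- cur
  }
  # spans recomputed by direct label scanning agree with the counts
  labs <- s$labels
  l <- ncol(labs)
  direct <- vapply(seq_len(nrow(labs)), function(i) {
    sum(table(labs[i, ]) / l * 100 > 30)
  }, numeric(1))
  expect_equal(as.numeric(count_stable_communities(s, 30)), direct)
})

test_that("the singleton flag drops never-shared communities", {
  labs <- rbind(c(1, 1, 2, 2),
                c(1, 1, 3, 3))  # community 1 shared; 2 and 3 always alone
  p <- partition_from_labels(labs)
  s <- stability_matrix(p)
  expect_equal(count_stable_communities(s, 10), c(2L, 2L))
  expect_equal(count_stable_communities(s, 10, include_singletons = FALSE),
               c(1L, 1L))
})

test_that("community size curves report non-singleton count and mean size", {
  labs <- cbind(c(1, 2, 3, 4),     # all singletons
                c(1, 1, 1, 1),     # one community of all 4 nodes
                c(1, 1, 2, 3))     # one pair + two singletons
  p <- partition_from_labels(labs)
  curves <- community_size_curves(p)
  expect_equal(curves$n_nonsingleton, c(0L, 1L, 1L))
  expect_equal(curves$mean_size_pct, c(0, 100, 50))
})

test_that("the coarse plateau of the nested benchmark has the planted count", {
  res <- small_benchmark_partition()
  curves <- community_size_curves(res$partition)
  # at gamma just above 1 the background decouples the three 9-blocks
  coarse <- curves[curves$gamma > 1.3 & curves$gamma < 3, ]
  expect_true(all(coarse$n_nonsingleton == 3))
  expect_true(all(abs(coarse$mean_size_pct - 100 / 3) < 1e-9))
})

test_that("allegiance matches co-classification fractions", {
  b <- build_multiscale(multiscale_spec(two_cliques_graph(), 1, tau = 0,
                                        null = null_model("uniform", constant = 0.5)))
  e <- run_ensemble(b, n_runs = 4, base_seed = 1)
  al <- allegiance(e)
  # identical runs: entries are exactly 0 or 1, diagonal 1, symmetric
  expect_true(all(al$intra[[1]] %in% c(0, 1)))
  expect_equal(diag(al$intra[[1]]), rep(1, 6))
  expect_equal(al$intra[[1]], t(al$intra[[1]]))
  expect_equal(al$intra[[1]][1, 2], 1)
  expect_equal(al$intra[[1]][1, 4], 0)

  # hand-built ensemble where two runs disagree on one pair
  labs1 <- c(1, 1, 2)
  labs2 <- c(1, 2, 2)
  g3 <- weighted_graph(matrix(0.5, 3, 3) - diag(0.5, 3))
  b3 <- build_multiscale(multiscale_spec(g3, 1, tau = 0,
                                         null = null_model("uniform", constant = 0.1)))
  e2 <- structure(list(runs = list(multiscale_partition(labs1, b3),
                                   multiscale_partition(labs2, b3)),
                       seeds = 1:2, n_nodes = 3L, n_layers = 1L,
                       layout = b3$layout, gamma_grid = 1),
                  class = "partition_ensemble")
  al2 <- allegiance(e2)
  expect_equal(al2$intra[[1]][1, 2], 0.5)
  expect_equal(al2$intra[[1]][2, 3], 0.5)
  expect_equal(al2$intra[[1]][1, 3], 0)
})

test_that("random-label allegiance concentrates near 1/C", {
  n <- 40L; c_labels <- 4L; n_runs <- 60L
  g <- weighted_graph(matrix(0.5, n, n) - diag(0.5, n))
  b <- build_multiscale(multiscale_spec(g, 1, tau = 0,
                                        null = null_model("uniform", constant = 0.1)))
  set.seed(99)
  runs <- lapply(seq_len(n_runs), function(r) {
    multiscale_partition(sample.int(c_labels, n, replace = TRUE), b)
  })
  e <- structure(list(runs = runs, seeds = seq_len(n_runs), n_nodes = n,
                      n_layers = 1L, layout = b$layout, gamma_grid = 1),
                 class = "partition_ensemble")
  al <- allegiance(e)
  off <- al$intra[[1]][upper.tri(al$intra[[1]])]
  expect_lt(abs(mean(off) - 1 / c_labels), 0.02)
})

test_that("inter-layer allegiance tracks label persistence", {
  labs_a <- cbind(c(1, 1), c(1, 1))  # persists
  labs_b <- cbind(c(1, 1), c(2, 2))  # switches
  g2 <- weighted_graph(matrix(c(0, 1, 1, 0), 2, 2))
  b2 <- build_multiscale(multiscale_spec(g2, c(1, 2), tau = 0.1,
                                         null = null_model("uniform", constant = 0.5)))
  e <- structure(list(runs = list(multiscale_partition(as.vector(labs_a), b2),
                                  multiscale_partition(as.vector(labs_b), b2)),
                      seeds = 1:2, n_nodes = 2L, n_layers = 2L,
                      layout = b2$layout, gamma_grid = c(1, 2)),
                 class = "partition_ensemble")
  al <- allegiance(e)
  expect_equal(al$inter[, 1], c(0.5, 0.5))
})

test_that("PCA component counts match an independent SVD computation", {
  # rank-2 stability-like matrix from two orthogonal row patterns
  r1 <- c(1, 1, 0, 0); r2 <- c(0, 0, 1, 1)
  vals <- rbind(r1, r1, r2, r2, r1, r2) * 0.6 + 0.2
  s <- structure(list(values = vals, labels = matrix(1L, 6, 4), n_layers = 4L),
                 class = "stability_matrix")
  expect_equal(heterogeneity_pca(s), 1L)  # after centering: rank 1
  vals2 <- vals
  vals2[1, ] <- c(0.9, 0.1, 0.5, 0.5)
  s2 <- structure(list(values = vals2, labels = matrix(1L, 6, 4), n_layers = 4L),
                  class = "stability_matrix")
  sv <- svd(scale(vals2, center = TRUE, scale = FALSE))$d
  ev <- cumsum(sv^2) / sum(sv^2) * 100
  expect_equal(heterogeneity_pca(s2), as.integer(which(ev >= 95)[1]))

  # exactly constant matrix: zero variance, 0 components with a warning
  s0 <- structure(list(values = matrix(0.5, 5, 4), labels = matrix(1L, 5, 4),
                       n_layers = 4L),
                  class = "stability_matrix")
  expect_warning(expect_equal(heterogeneity_pca(s0), 0L), "constant")

  # on the benchmark: same count as direct SVD of the centered matrix
  res <- small_benchmark_partition()
  sb <- stability_matrix(res$partition)
  svb <- svd(scale(sb$values, center = TRUE, scale = FALSE))$d
  evb <- cumsum(svb^2) / sum(svb^2) * 100
  expect_equal(heterogeneity_pca(sb), as.integer(which(evb >= 95)[1]))
})
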