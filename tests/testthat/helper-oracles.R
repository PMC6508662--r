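# Independent oracles used to freeze expected values. These deliberately
# avoid the code paths they check: partition enumeration is a direct
# restricted-growth-string recursion, qualities are dense-matrix sums, and
# connected components are a hand-rolled BFS.

# all set partitions of 1..n as label vectors (Bell(n) of them)
enumerate_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, next_label) {
    k <- length(labels)
    if (k == n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (lab in seq_len(next_label)) {
      recurse(c(labels, lab), max(next_label, lab + 1L))
    }
  }
  recurse(integer(0), 1L)
  out
}

# raw quality (2*mu*Q) of a label vector against a dense coefficient matrix,
# diagonal excluded
dense_quality <- function(bd, labels) {
  same <- outer(labels, labels, "==")
  diag(same) <- FALSE
  sum(bd[same])
}

# exhaustive optimum over all partitions of the node-layers of b
brute_force_optimum <- function(b) {
  bd <- as.matrix(b$matrix)
  parts <- enumerate_partitions(nrow(bd))
  qs <- vapply(parts, function(p) dense_quality(bd, p), numeric(1L))
  best <- which.max(qs)
  list(q_raw = qs[best], labels = parts[[best]], n_partitions = length(parts))
}

# number of connected components among `members` in a binary adjacency
# matrix, by BFS
bfs_component_count <- function(adj, members) {
  remaining <- members
  n_comp <- 0L
  while (length(remaining)) {
    n_comp <- n_comp + 1L
    queue <- remaining[1L]
    seen <- queue
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- intersect(which(adj[v, ] > 0), remaining)
      new <- setdiff(nb, seen)
      seen <- c(seen, new)
      queue <- c(queue, new)
    }
    remaining <- setdiff(remaining, seen)
  }
  n_comp
}
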