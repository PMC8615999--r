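star4 <- function() {
  a <- matrix(0L, 4, 4); a[1, 2:4] <- a[2:4, 1] <- 1L
  binarize(a, 0.5)
}

test_that("K-order neighbourhood counts match hand enumeration", {
  set.seed(41)
  G <- binarize(rand_adj(6, 0.4), 0.5)
  L <- shortest_paths_matrix(G)
  expect_equal(k_neighbourhood_counts(L, 0), rep(1L, 6))

  Ls <- shortest_paths_matrix(star4())
  expect_equal(k_neighbourhood_counts(Ls, 1), c(4L, 2L, 2L, 2L))

  p <- matrix(0L, 3, 3); p[1, 2] <- p[2, 1] <- p[2, 3] <- p[3, 2] <- 1L
  Lp <- shortest_paths_matrix(binarize(p, 0.5))
  expect_equal(k_neighbourhood_counts(Lp, 1), c(2L, 3L, 2L))
  expect_error(k_neighbourhood_counts(Lp, -1), "nonnegative")
})

test_that("K-order structure entropy: maximum at uniform counts, frozen values", {
  expect_equal(k_order_entropy(rep(3, 7)), log(7))
  expect_equal(k_order_entropy(c(4, 2, 2, 2)), 1.3322, tolerance = 1e-3)
  expect_equal(k_order_entropy(c(2, 3, 2)), 1.0789, tolerance = 1e-3)
  # strictly below ln n when counts are non-uniform
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    counts <- sample(1:5, n, replace = TRUE)
    H <- k_order_entropy(counts)
    expect_lte(H, log(n) + 1e-12)
    if (max(counts) > min(counts)) expect_lt(H, log(n))
  }
  expect_error(k_order_entropy(numeric(0)), "empty")
})

test_that("count normalization and entropy weights, incl. degenerate conventions", {
  expect_equal(normalize_counts(c(4, 2, 2, 2)), c(1, 0, 0, 0))
  expect_equal(normalize_counts(c(1, 1, 1)), c(0, 0, 0))
  expect_equal(normalize_counts(c(2, 3, 4)), c(0, 0.5, 1))

  expect_equal(entropy_weights(c(1.3863, 1.3322, 1.3863)), c(0, 1, 0))
  expect_equal(entropy_weights(rep(1.1, 3)), rep(1 / 3, 3))
  set.seed(43)
  for (rep in 1:5) {
    H <- runif(4)
    expect_equal(entropy_weights(H)[which.min(H)], 1)
  }
})

test_that("node importance: star center 1 / leaves 0, complete graphs uniform", {
  imp <- node_importance(star4())
  expect_equal(unname(imp$Q), c(1, 0, 0, 0))
  expect_equal(imp$profile$d, 2L)
  expect_equal(imp$profile$H[1], log(4))  # H_0 = ln n always
  for (n in c(3, 5, 8)) {
    a <- matrix(1L, n, n); diag(a) <- 0L
    Q <- node_importance(binarize(a, 0.5))$Q
    expect_equal(unname(Q), rep(Q[[1]], n))
  }
})

test_that("pipeline importance equals the straight-line oracle on random graphs", {
  set.seed(44)
  for (rep in 1:30) {
    n <- sample(3:10, 1)
    adj <- rand_adj(n, runif(1, 0.1, 0.8))
    Q <- unname(node_importance(binarize(adj, 0.5))$Q)
    expect_equal(Q, oracle_kprop(adj), tolerance = 1e-12)
  }
  # structured families at n <= 6 (paths, stars, cycles, empty, complete)
  for (n in 3:6) {
    fams <- list(
      diag(0L, n),
      { a <- matrix(1L, n, n); diag(a) <- 0L; a },
      { a <- matrix(0L, n, n); a[1, 2:n] <- a[2:n, 1] <- 1L; a },
      { a <- matrix(0L, n, n); for (i in 1:(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1L; a },
      { a <- matrix(0L, n, n); for (i in 1:(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1L
        a[1, n] <- a[n, 1] <- 1L; a })
    for (adj in fams) {
      expect_equal(unname(node_importance(binarize(adj, 0.5))$Q),
                   oracle_kprop(adj), tolerance = 1e-12)
    }
  }
})

test_that("Q is invariant to the entropy logarithm base", {
  set.seed(45)
  for (rep in 1:10) {
    adj <- rand_adj(sample(4:9, 1), 0.4)
    expect_equal(oracle_kprop(adj, base = 2), oracle_kprop(adj, base = exp(1)),
                 tolerance = 1e-10)
    expect_equal(unname(node_importance(binarize(adj, 0.5))$Q),
                 oracle_kprop(adj, base = 10), tolerance = 1e-10)
  }
})

test_that("count profiles are monotone in K and reach the component size", {
  set.seed(46)
  for (rep in 1:10) {
    n <- sample(5:10, 1)
    G <- binarize(rand_adj(n, 0.25), 0.5)
    imp <- node_importance(G)
    counts <- imp$profile$counts
    if (ncol(counts) > 1) {
      expect_true(all(apply(counts, 1, function(r) all(diff(r) >= 0))))
    }
    comp <- igraph::components(
      igraph::graph_from_adjacency_matrix(G$adjacency, mode = "undirected"))
    expect_equal(counts[, ncol(counts)], comp$csize[comp$membership],
                 ignore_attr = TRUE)
    expect_true(all(imp$Q >= 0 & imp$Q <= imp$profile$d + 1))
  }
})

test_that("connecting an isolated node never decreases its importance", {
  set.seed(47)
  for (rep in 1:10) {
    n <- sample(5:9, 1)
    adj <- rand_adj(n, 0.4)
    adj[n, ] <- adj[, n] <- 0L                      # isolate node n
    q_before <- oracle_kprop(adj)[n]
    adj2 <- adj
    tgt <- sample(seq_len(n - 1), 1)
    adj2[n, tgt] <- adj2[tgt, n] <- 1L
    q_after <- oracle_kprop(adj2)[n]
    expect_gte(q_after, q_before)
    expect_equal(unname(node_importance(binarize(adj2, 0.5))$Q),
                 oracle_kprop(adj2), tolerance = 1e-12)
  }
})

test_that("feature vectors respect the ordering policy", {
  Q <- c(a = 0.2, b = 0.9, c = 0.5)
  expect_equal(feature_vector(Q, "channel"), c(0.2, 0.9, 0.5), ignore_attr = TRUE)
  expect_equal(feature_vector(Q, "sorted_desc"), c(0.9, 0.5, 0.2))
  expect_equal(feature_vector(Q[c(2, 3, 1)], "sorted_desc"),
               feature_vector(Q, "sorted_desc"))
  expect_error(feature_vector(Q, "upside_down"))
})
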