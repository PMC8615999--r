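test_that("cross-sample entropy matches hand-derivable cases", {
  # identical monotone series: only aligned templates match at both lengths
  expect_equal(cross_sample_entropy(1:6, 1:6, csen_params(m = 2, r = 0.5)), 0)
  # identical constant series: all template pairs match at both lengths
  expect_equal(cross_sample_entropy(rep(2, 10), rep(2, 10), csen_params(m = 2, r = 0.1)), 0)
})

test_that("undefined entropy follows the configured policy", {
  x <- c(0, 10, 0, 10, 0, 10)
  y <- c(100, 200, 100, 200, 100, 200)
  expect_error(
    cross_sample_entropy(x, y, csen_params(m = 2, r = 0.5, undefined = "strict")),
    "undefined entropy")
  # cap: -ln(1 / (N - m)^2) = ln(16) for N = 6, m = 2
  expect_equal(cross_sample_entropy(x, y, csen_params(m = 2, r = 0.5)), log(16))
})

test_that("CsEn agrees with the brute-force oracle on random pairs", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(10:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    r <- 0.2 * sd(c(x, y))
    got <- tryCatch(
      cross_sample_entropy(x, y, csen_params(m = 2, r = r, undefined = "strict")),
      error = function(e) NA_real_)
    expect_equal(got, oracle_csen(x, y, 2, r), tolerance = 1e-12)
  }
})

test_that("CsEn is symmetric and nonnegative", {
  set.seed(22)
  for (rep in 1:10) {
    x <- rnorm(30); y <- rnorm(30)
    p <- csen_params(m = 2, r = 0.25)
    e1 <- cross_sample_entropy(x, y, p)
    e2 <- cross_sample_entropy(y, x, p)
    expect_identical(e1, e2)
    expect_gte(e1, 0)
  }
})

test_that("connectivity_matrix equals entrywise recomputation and is symmetric", {
  set.seed(23)
  ep <- matrix(rnorm(5 * 60), nrow = 5)
  params <- csen_params(m = 2, r_coeff = 0.2)
  A <- connectivity_matrix(ep, params)
  expect_identical(A$values, t(A$values))
  expect_true(all(diag(A$values) == 0))
  for (i in 1:4) {
    for (j in (i + 1):5) {
      r <- 0.2 * sd(c(ep[i, ], ep[j, ]))  # per-pair pooled-SD tolerance
      exp_ij <- oracle_csen(ep[i, ], ep[j, ], 2, r)
      if (is.na(exp_ij)) exp_ij <- log((60 - 2)^2)
      expect_equal(A$values[i, j], exp_ij, tolerance = 1e-12)
    }
  }
})

test_that("identical channels reproduce the pairwise self-entropy", {
  set.seed(24)
  x <- rnorm(50)
  ep <- rbind(x, x)
  A <- connectivity_matrix(ep, csen_params(m = 2, r = 0.3))
  expect_equal(A$values[1, 2],
               cross_sample_entropy(x, x, csen_params(m = 2, r = 0.3)))
})

test_that("connectivity_matrix is permutation-equivariant", {
  set.seed(25)
  ep <- matrix(rnorm(4 * 50), nrow = 4)
  rownames(ep) <- paste0("c", 1:4)
  perm <- c(3, 1, 4, 2)
  A <- connectivity_matrix(ep, csen_params(m = 2, r = 0.3))
  Ap <- connectivity_matrix(ep[perm, ], csen_params(m = 2, r = 0.3))
  expect_equal(unname(Ap$values), unname(A$values[perm, perm]), tolerance = 1e-12)
})

test_that("normalize_matrix rescales off-diagonals to [0,1]", {
  v <- matrix(0, 3, 3)
  v[1, 2] <- v[2, 1] <- 0.2; v[1, 3] <- v[3, 1] <- 0.5; v[2, 3] <- v[3, 2] <- 0.8
  A <- structure(list(values = v, channel_labels = paste0("c", 1:3),
                      normalized = FALSE, n_capped = 0L), class = "kfcs_conn")
  N <- normalize_matrix(A)
  expect_equal(N$values[1, 2], 0); expect_equal(N$values[1, 3], 0.5)
  expect_equal(N$values[2, 3], 1); expect_true(N$normalized)
  # idempotent on full-range input
  expect_equal(normalize_matrix(N)$values, N$values)
  v[] <- 0.4; diag(v) <- 0; A$values <- v
  A$values[1, 2] <- A$values[2, 1] <- 0.4
  A$values[1, 3] <- A$values[3, 1] <- 0.4; A$values[2, 3] <- A$values[3, 2] <- 0.4
  expect_error(normalize_matrix(A), "degenerate")
})

test_that("mean_csen averages off-diagonal entries", {
  mk <- function(val) {
    v <- matrix(val, 2, 2); diag(v) <- 0
    structure(list(values = v, channel_labels = c("a", "b"),
                   normalized = FALSE, n_capped = 0L), class = "kfcs_conn")
  }
  expect_equal(mean_csen(list(mk(1))), 1)
  expect_equal(mean_csen(list(mk(0.2), mk(0.6))), 0.4)
  expect_error(mean_csen(list()), "empty")
})

test_that("planted hub coupling lowers the raw group-level mean CsEn", {
  cfg <- synth_config(n_channels = 12, fs = 250, n_epochs_per_class = 5,
                      hub_channels = 1:3, seed = 12)  # braking gain 2*sd, normal 0
  es <- generate_epoch_set(cfg)
  raw <- epoch_connectivity(es, normalize = FALSE)
  expect_lt(mean_csen(raw[es$labels == "braking"]),
            mean_csen(raw[es$labels == "normal"]))
})

test_that("connectivity matrices round-trip through TSV", {
  set.seed(26)
  A <- connectivity_matrix(matrix(rnorm(3 * 40), 3), csen_params(m = 2, r = 0.3))
  path <- tempfile(fileext = ".tsv")
  write_conn_tsv(A, path)
  B <- read_conn_tsv(path)
  expect_equal(B$values, A$values, tolerance = 1e-12)
  expect_identical(B$channel_labels, A$channel_labels)
})
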