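# Independent oracles. These deliberately share no helpers with the package:
# brute-force template matching for CsEn, Floyd-Warshall for distances, and a
# straight-line transcription of the K-order importance formulas.

oracle_csen <- function(x, y, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0L; B <- 0L
  for (i in seq_len(nt)) {
    for (j in seq_len(nt)) {
      dm <- max(abs(x[i:(i + m - 1)] - y[j:(j + m - 1)]))
      if (dm <= r) {
        B <- B + 1L
        if (max(dm, abs(x[i + m] - y[j + m])) <= r) A <- A + 1L
      }
    }
  }
  if (A == 0L || B == 0L) return(NA_real_)  # undefined
  -log(A / B)
}

oracle_floyd <- function(adj) {
  n <- nrow(adj)
  l <- matrix(Inf, n, n)
  diag(l) <- 0
  l[adj == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (l[i, k] + l[k, j] < l[i, j]) l[i, j] <- l[i, k] + l[k, j]
      }
    }
  }
  l
}

# Straight-line K-order importance: distances, diameter, counts, entropy,
# min-max normalization, entropy weights, weighted sum. `base` exercises the
# claim that Q is invariant to the entropy logarithm base.
oracle_kprop <- function(adj, base = exp(1)) {
  n <- nrow(adj)
  l <- oracle_floyd(adj)
  d <- max(l[is.finite(l)])
  Q <- rep(0, n)
  H <- numeric(d + 1)
  S <- matrix(0, n, d + 1)
  for (K in 0:d) {
    N <- vapply(seq_len(n), function(i) sum(is.finite(l[i, ]) & l[i, ] <= K),
                numeric(1))
    p <- N / sum(N)
    H[K + 1] <- -sum(p * log(p, base = base))
    if (max(N) > min(N)) S[, K + 1] <- (N - min(N)) / (max(N) - min(N))
  }
  cK <- if (max(H) == min(H)) rep(1 / (d + 1), d + 1) else 1 - (H - min(H)) / (max(H) - min(H))
  as.numeric(S %*% cK)
}

rand_adj <- function(n, p = 0.4) {
  a <- matrix(0L, n, n)
  up <- which(upper.tri(a))
  a[up] <- as.integer(runif(length(up)) < p)
  a + t(a)
}
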