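#' Cross-sample entropy parameters
#'
#' @param m embedding (template) dimension; integer >= 1. Default 2, the
#'   field's standard choice for 1-s EEG segments.
#' @param r_coeff tolerance as a fraction of the pooled standard deviation of
#'   the epoch; default 0.2. Used by [connectivity_matrix()] to resolve the
#'   absolute tolerance.
#' @param r optional absolute matching tolerance; when supplied it overrides
#'   `r_coeff`-based resolution.
#' @param undefined how to treat pairs with zero template matches, which do
#'   occur on short epochs: `"cap"` (default) replaces the undefined value by
#'   the maximum estimable entropy `ln((N - m)^2)`, `"strict"` raises an error.
#' @return A `kfcs_csen_params` list.
#' @export
csen_params <- function(m = 2, r_coeff = 0.2, r = NULL,
                        undefined = c("cap", "strict")) {
  undefined <- match.arg(undefined)
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m)) {
    stop("m must be an integer >= 1")
  }
  if (!is.null(r) && (!is.numeric(r) || r <= 0)) stop("r must be positive")
  if (is.null(r) && (!is.numeric(r_coeff) || r_coeff <= 0)) {
    stop("r_coeff must be positive")
  }
  structure(list(m = as.integer(m), r_coeff = r_coeff, r = r,
                 undefined = undefined),
            class = "kfcs_csen_params")
}

#' Cross-sample entropy between two series
#'
#' Richman–Moorman cross-SampEn: with `N` samples, templates of length `m`
#' (and `m + 1`) are taken at the first `N - m` positions of each series and
#' compared across series with the Chebyshev distance. With `B` matches at
#' length `m` and `A` at length `m + 1` within tolerance `r`, the entropy is
#' `-ln(A / B)`. Symmetric in its two arguments by construction; lower values
#' mean stronger shared dynamics.
#'
#' @param x,y numeric vectors of equal length `> m + 1`.
#' @param params a [csen_params()]; `params$r` must be set (absolute units).
#' @return Nonnegative scalar entropy.
#' @export
cross_sample_entropy <- function(x, y, params = csen_params(r = 0.2)) {
  stopifnot(inherits(params, "kfcs_csen_params"))
  if (is.null(params$r)) stop("cross_sample_entropy needs an absolute tolerance params$r")
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) <= params$m + 1L) stop("series length must exceed m + 1")
  ab <- csen_counts(as.numeric(x), as.numeric(y), params$m, params$r)
  csen_from_counts(ab[1], ab[2], length(x) - params$m, params$undefined)
}

csen_from_counts <- function(A, B, n_templates, undefined) {
  if (A > 0 && B > 0) return(-log(A / B))
  if (undefined == "strict") {
    stop("undefined entropy: no template matches at tolerance r")
  }
  log(n_templates^2)  # cap: -ln(1 / (N - m)^2)
}

#' Pairwise CsEn connectivity matrix of one epoch
#'
#' Computes [cross_sample_entropy()] for every channel pair and assembles the
#' symmetric weighted adjacency matrix with zero diagonal. When `params$r` is
#' `NULL` the tolerance is resolved per pair as `r_coeff` times the pooled
#' standard deviation of the two series (the field convention), so channels
#' with different amplitudes are compared on a common relative scale.
#'
#' @param epoch channels-by-samples numeric matrix, at least 2 channels.
#' @param params a [csen_params()].
#' @return A `kfcs_conn` object: fields `values` (symmetric matrix),
#'   `channel_labels`, `normalized` (logical), `n_capped`.
#' @export
connectivity_matrix <- function(epoch, params = csen_params()) {
  stopifnot(inherits(params, "kfcs_csen_params"))
  epoch <- as.matrix(epoch)
  nc <- nrow(epoch)
  if (nc < 2L) stop("need at least 2 channels")
  labels <- rownames(epoch)
  if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(nc))
  nt <- ncol(epoch) - params$m
  vals <- matrix(0, nc, nc, dimnames = list(labels, labels))
  n_capped <- 0L
  for (i in seq_len(nc - 1L)) {
    for (j in (i + 1L):nc) {
      r <- params$r
      if (is.null(r)) r <- params$r_coeff * stats::sd(c(epoch[i, ], epoch[j, ]))
      if (!is.finite(r) || r <= 0) stop("resolved tolerance r is not positive")
      ab <- csen_counts(epoch[i, ], epoch[j, ], params$m, r)
      if (ab[1] <= 0 || ab[2] <= 0) n_capped <- n_capped + 1L
      e <- csen_from_counts(ab[1], ab[2], nt, params$undefined)
      vals[i, j] <- vals[j, i] <- e
    }
  }
  structure(list(values = vals, channel_labels = labels,
                 normalized = FALSE, n_capped = n_capped),
            class = "kfcs_conn")
}

#' @export
print.kfcs_conn <- function(x, ...) {
  off <- offdiag(x$values)
  cat(sprintf("<kfcs_conn> %d x %d%s; off-diagonal range [%.4g, %.4g]%s\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) " (normalized)" else "",
              min(off), max(off),
              if (x$n_capped > 0) sprintf("; %d capped entries", x$n_capped) else ""))
  invisible(x)
}

offdiag <- function(m) m[row(m) != col(m)]

#' Min-max normalize a connectivity matrix
#'
#' Rescales the off-diagonal entries to `[0, 1]`; the diagonal stays 0 and is
#' excluded from all statistics.
#'
#' @param A a `kfcs_conn` from [connectivity_matrix()].
#' @return A normalized `kfcs_conn`.
#' @export
normalize_matrix <- function(A) {
  stopifnot(inherits(A, "kfcs_conn"))
  off <- offdiag(A$values)
  lo <- min(off); hi <- max(off)
  if (hi == lo) stop("degenerate matrix: all off-diagonal values equal")
  v <- (A$values - lo) / (hi - lo)
  diag(v) <- 0
  A$values <- v
  A$normalized <- TRUE
  A
}

#' Mean CsEn over a set of connectivity matrices
#'
#' Arithmetic mean over all off-diagonal entries of all matrices; used to
#' compare group-level connectivity between the two driving states (braking
#' epochs show lower mean CsEn than normal driving when hub coupling is
#' present).
#'
#' @param matrices non-empty list of same-shape `kfcs_conn` objects.
#' @return Scalar mean.
#' @export
mean_csen <- function(matrices) {
  if (length(matrices) == 0L) stop("empty matrix list")
  stopifnot(all(vapply(matrices, inherits, logical(1), "kfcs_conn")))
  dims <- vapply(matrices, function(m) dim(m$values), integer(2))
  if (any(dims != dims[, 1])) stop("matrices must share one shape")
  mean(vapply(matrices, function(m) mean(offdiag(m$values)), numeric(1)))
}

#' Export / import a connectivity matrix as TSV
#'
#' TSV with channel labels as header row and first column.
#'
#' @param A a `kfcs_conn`.
#' @param path file path.
#' @return `write_conn_tsv`: `path` invisibly; `read_conn_tsv`: a `kfcs_conn`.
#' @export
write_conn_tsv <- function(A, path) {
  stopifnot(inherits(A, "kfcs_conn"))
  df <- data.frame(channel = A$channel_labels, A$values, check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_conn_tsv
#' @param normalized flag recorded on the imported matrix.
#' @export
read_conn_tsv <- function(path, normalized = FALSE) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  labels <- as.character(df[[1]])
  v <- as.matrix(df[, -1, drop = FALSE])
  dimnames(v) <- list(labels, labels)
  if (!isTRUE(all.equal(v, t(v)))) stop("imported matrix is not symmetric")
  structure(list(values = v, channel_labels = labels,
                 normalized = normalized, n_capped = 0L),
            class = "kfcs_conn")
}
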