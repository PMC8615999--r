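# K-order propagation number node importance. The per-node count N_vi^K is
# the size of v_i's K-hop neighbourhood including itself; the entropy of the
# count distribution across nodes (H_K) measures network heterogeneity at
# scale K, and importance Q_vi is the entropy-weighted sum over K of the
# min-max-normalized counts.

#' K-order neighbourhood counts
#'
#' `N_vi^K = 1 + |{ j != i : l_ij <= K, l_ij finite }|` — the number of nodes
#' a node can reach within `K` hops, counting itself. Unreachable pairs never
#' satisfy the condition.
#'
#' @param L a `kfcs_dist` from [shortest_paths_matrix()], or a plain distance
#'   matrix (`Inf` for unreachable).
#' @param K step size, integer >= 0.
#' @return Integer vector of per-node counts (all >= 1).
#' @export
k_neighbourhood_counts <- function(L, K) {
  if (inherits(L, "kfcs_dist")) L <- L$l
  if (K < 0) stop("K must be nonnegative")
  counts <- rowSums(is.finite(L) & L <= K)  # includes the node itself (l_ii = 0)
  as.integer(counts)
}

#' K-order structure entropy
#'
#' Shannon entropy (natural log) of the neighbourhood counts normalized to a
#' probability distribution: `H = -sum_i p_i ln p_i`, `p_i = N_i / sum_j N_j`.
#' Maximal (`ln n`) iff the counts are uniform.
#'
#' @param NK positive per-node counts.
#' @return Scalar entropy in `[0, ln n]`.
#' @export
k_order_entropy <- function(NK) {
  if (length(NK) == 0L) stop("empty count vector")
  if (any(NK < 1)) stop("counts must be >= 1")
  p <- NK / sum(NK)
  -sum(p * log(p))
}

#' Min-max normalize neighbourhood counts
#'
#' `S_vi = (N_vi - min) / (max - min)`; when all counts are equal the
#' degenerate convention sets every `S_vi = 0`, so vertex-transitive graphs
#' contribute nothing at that scale.
#'
#' @param NK per-node counts.
#' @return Numeric vector in `[0, 1]`.
#' @export
normalize_counts <- function(NK) {
  if (length(NK) == 0L) stop("empty count vector")
  lo <- min(NK); hi <- max(NK)
  if (hi == lo) return(rep(0, length(NK)))
  (NK - lo) / (hi - lo)
}

#' Entropy weights over scales K
#'
#' `c_K = 1 - (H_K - min H) / (max H - min H)`: the scale with the lowest
#' entropy — the greatest node-importance differences — gets full weight 1.
#' When all `H_K` are equal the weights are uniform `1 / (d + 1)`.
#'
#' @param H vector of entropies for `K = 0..d`.
#' @return Weights in `[0, 1]`, same length as `H`.
#' @export
entropy_weights <- function(H) {
  if (length(H) == 0L) stop("empty entropy vector")
  lo <- min(H); hi <- max(H)
  if (hi == lo) return(rep(1 / length(H), length(H)))
  1 - (H - lo) / (hi - lo)
}

#' K-order propagation number node importance
#'
#' For a binary network: computes shortest paths and the diameter `d`, then
#' for each `K` in `0..d` the neighbourhood counts `N^K`, structure entropy
#' `H_K`, normalized counts `S^K` and weight `c_K`, and finally
#' `Q_vi = sum_K c_K * S_vi^K`. `Q` is invariant to the logarithm base used
#' in `H_K` (the min-max in the weights cancels any rescaling).
#'
#' @param G a `kfcs_binnet`.
#' @return A `kfcs_importance`: fields `Q` (named per-node scores), `profile`
#'   (list with `d`, `K`, `counts`, `H`, `S`, `c`), `channel_labels`.
#' @export
node_importance <- function(G) {
  stopifnot(inherits(G, "kfcs_binnet"))
  L <- shortest_paths_matrix(G)
  d <- net_diameter(L)
  Ks <- 0:d
  counts <- vapply(Ks, function(K) k_neighbourhood_counts(L, K),
                   integer(nrow(G$adjacency)))
  counts <- matrix(counts, nrow = nrow(G$adjacency))  # nodes x (d+1)
  H <- apply(counts, 2L, k_order_entropy)
  S <- apply(counts, 2L, normalize_counts)
  S <- matrix(S, nrow = nrow(counts))
  cK <- entropy_weights(H)
  Q <- as.numeric(S %*% cK)
  names(Q) <- G$channel_labels
  structure(list(Q = Q,
                 profile = list(d = d, K = Ks, counts = counts, H = H,
                                S = S, c = cK),
                 channel_labels = G$channel_labels),
            class = "kfcs_importance")
}

#' @export
print.kfcs_importance <- function(x, ...) {
  cat(sprintf("<kfcs_importance> %d nodes, diameter %d; top: %s\n",
              length(x$Q), x$profile$d,
              paste(names(sort(x$Q, decreasing = TRUE))[seq_len(min(3, length(x$Q)))],
                    collapse = ", ")))
  invisible(x)
}

#' Feature vector from node importance
#'
#' `ordering = "channel"` (default) keeps `Q` in channel order, preserving
#' the spatial identity needed for regional channel grouping;
#' `"sorted_desc"` sorts descending, losing channel identity but invariant
#' to channel relabelling.
#'
#' @param imp a `kfcs_importance` (or bare numeric Q vector).
#' @param ordering `"channel"` or `"sorted_desc"`.
#' @return Numeric vector of length n.
#' @export
feature_vector <- function(imp, ordering = c("channel", "sorted_desc")) {
  ordering <- match.arg(ordering)
  Q <- if (inherits(imp, "kfcs_importance")) imp$Q else as.numeric(imp)
  if (ordering == "channel") Q else sort(unname(Q), decreasing = TRUE)
}
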