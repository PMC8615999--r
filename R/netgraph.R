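#' Binarize a weighted connectivity matrix at threshold Tri
#'
#' The default rule `ge` places an edge where the weight is at least `tri`,
#' so raising the threshold makes the network sparser (edge sets are nested
#' under increasing `tri`). Rule `le` is offered for the reading in which low
#' entropy = strong correlation = edge.
#'
#' @param A a `kfcs_conn` (raw or normalized — caller's choice) or a plain
#'   symmetric numeric matrix.
#' @param tri threshold value.
#' @param rule `"ge"` (default) or `"le"`.
#' @return A `kfcs_binnet`: fields `adjacency` (0/1 matrix, zero diagonal)
#'   and `channel_labels`.
#' @export
binarize <- function(A, tri, rule = c("ge", "le")) {
  rule <- match.arg(rule)
  if (inherits(A, "kfcs_conn")) {
    v <- A$values
    labels <- A$channel_labels
  } else {
    v <- as.matrix(A)
    labels <- rownames(v)
    if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(nrow(v)))
  }
  adj <- if (rule == "ge") (v >= tri) else (v <= tri)
  adj <- adj * 1L
  storage.mode(adj) <- "integer"
  diag(adj) <- 0L
  dimnames(adj) <- list(labels, labels)
  structure(list(adjacency = adj, channel_labels = labels),
            class = "kfcs_binnet")
}

#' @export
print.kfcs_binnet <- function(x, ...) {
  n <- nrow(x$adjacency)
  ne <- sum(x$adjacency) / 2
  cat(sprintf("<kfcs_binnet> %d nodes, %d edges (density %.3f)\n",
              n, ne, if (n > 1) ne / (n * (n - 1) / 2) else 0))
  invisible(x)
}

#' Z-score network-density threshold
#'
#' Expresses a binarization threshold as a deviation from the average
#' connectivity level: `mean + z * sd` over the off-diagonal entries (sample
#' sd, n-1 denominator). Larger `z` gives a sparser network under rule `ge`.
#'
#' @param A a `kfcs_conn`.
#' @param z Z-score.
#' @return The threshold value.
#' @export
threshold_from_zscore <- function(A, z) {
  stopifnot(inherits(A, "kfcs_conn"))
  off <- offdiag(A$values)
  if (min(off) == max(off)) stop("degenerate matrix: all off-diagonal values equal")
  mean(off) + z * stats::sd(off)
}

#' Unweighted shortest-path length matrix
#'
#' Breadth-first shortest-path lengths between all node pairs; unreachable
#' pairs are marked `Inf`.
#'
#' @param G a `kfcs_binnet`.
#' @return A `kfcs_dist`: field `l`, an n x n matrix of path lengths.
#' @export
shortest_paths_matrix <- function(G) {
  stopifnot(inherits(G, "kfcs_binnet"))
  g <- igraph::graph_from_adjacency_matrix(G$adjacency, mode = "undirected",
                                           diag = FALSE)
  l <- igraph::distances(g, algorithm = "unweighted")
  dimnames(l) <- dimnames(G$adjacency)
  structure(list(l = l, channel_labels = G$channel_labels),
            class = "kfcs_dist")
}

#' Network diameter
#'
#' Longest finite shortest-path length. On disconnected graphs unreachable
#' pairs are ignored (maximum over finite distances); an edgeless graph has
#' diameter 0.
#'
#' @param G a `kfcs_binnet` or a `kfcs_dist`.
#' @return Nonnegative integer.
#' @export
net_diameter <- function(G) {
  l <- if (inherits(G, "kfcs_dist")) G$l else shortest_paths_matrix(G)$l
  fin <- l[is.finite(l)]
  as.integer(max(fin))
}

#' Export a binary network as an edge list
#'
#' TSV with two columns (`label_i`, `label_j`), one undirected edge per row,
#' for external topographic plotting.
#'
#' @param G a `kfcs_binnet`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(G, path) {
  stopifnot(inherits(G, "kfcs_binnet"))
  idx <- which(upper.tri(G$adjacency) & G$adjacency == 1L, arr.ind = TRUE)
  df <- data.frame(label_i = G$channel_labels[idx[, 1]],
                   label_j = G$channel_labels[idx[, 2]])
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
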