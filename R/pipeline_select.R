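#' Importance features for every epoch at one threshold
#'
#' Binarizes each epoch's connectivity matrix at `tri` and extracts the
#' per-channel importance Q as that epoch's feature row (channel ordering,
#' preserving spatial identity).
#'
#' @param conns list of `kfcs_conn`, one per epoch.
#' @param labels epoch labels.
#' @param tri binarization threshold.
#' @param rule edge rule passed to [binarize()].
#' @param subject_id subject identifier.
#' @return A [feature_table()].
#' @export
features_at_threshold <- function(conns, labels, tri, rule = "ge",
                                  subject_id = "S1") {
  X <- t(vapply(conns, function(cm) {
    feature_vector(node_importance(binarize(cm, tri, rule)))
  }, numeric(nrow(conns[[1]]$values))))
  colnames(X) <- conns[[1]]$channel_labels
  feature_table(X, labels, subject_id)
}

#' Per-epoch connectivity matrices of an epoch set
#'
#' @param epochs a [epoch_set()].
#' @param params a [csen_params()].
#' @param normalize min-max normalize each matrix (default `TRUE`, matching
#'   the per-matrix normalization convention).
#' @return List of `kfcs_conn`.
#' @export
epoch_connectivity <- function(epochs, params = csen_params(), normalize = TRUE) {
  stopifnot(inherits(epochs, "kfcs_epochs"))
  lapply(epochs$epochs, function(ep) {
    cm <- connectivity_matrix(ep, params)
    if (normalize) cm <- normalize_matrix(cm)
    cm
  })
}

#' Threshold sweep with cross-validated accuracy
#'
#' The Tri grid is `grid_size` evenly spaced values between the global
#' minimum and maximum off-diagonal weight across the subject's matrices.
#' For each Tri every epoch's matrix is binarized, importance features are
#' extracted and scored with [train_and_score()]; the best threshold is the
#' accuracy argmax, ties broken toward the smallest Tri.
#'
#' @param epochs a [epoch_set()] (already preprocessed), or a list of
#'   precomputed `kfcs_conn` via the `conns` argument.
#' @param grid_size number of grid points (default 50).
#' @param params a [csen_params()].
#' @param folds,seed cross-validation controls.
#' @param rule edge rule for [binarize()].
#' @param normalize per-matrix normalization flag for [epoch_connectivity()].
#' @param conns optional precomputed connectivity list (skips CsEn).
#' @param labels required with `conns`.
#' @return A `kfcs_sweep`: fields `grid`, `accuracy`, `best_tri`,
#'   `best_accuracy`, `subject_id`.
#' @export
threshold_sweep <- function(epochs = NULL, grid_size = 50,
                            params = csen_params(), folds = 10, seed = 1,
                            rule = "ge", normalize = TRUE,
                            conns = NULL, labels = NULL) {
  if (grid_size < 2L) stop("grid_size must be >= 2")
  subject_id <- "S1"
  if (is.null(conns)) {
    stopifnot(inherits(epochs, "kfcs_epochs"))
    conns <- epoch_connectivity(epochs, params, normalize)
    labels <- epochs$labels
    subject_id <- epochs$subject_id
  }
  if (is.null(labels)) stop("labels required with precomputed conns")
  offs <- unlist(lapply(conns, function(cm) offdiag(cm$values)))
  lo <- min(offs); hi <- max(offs)
  if (lo == hi) stop("degenerate matrices: no weight spread to sweep")
  grid <- seq(lo, hi, length.out = grid_size)
  acc <- vapply(grid, function(tri) {
    ft <- features_at_threshold(conns, labels, tri, rule, subject_id)
    train_and_score(ft, folds = folds, seed = seed)
  }, numeric(1))
  best <- which.max(acc)  # first maximum = smallest Tri on ties
  structure(list(grid = grid, accuracy = acc,
                 best_tri = grid[best], best_accuracy = acc[best],
                 subject_id = subject_id, folds = folds, seed = seed,
                 rule = rule),
            class = "kfcs_sweep")
}

#' @export
print.kfcs_sweep <- function(x, ...) {
  cat(sprintf("<kfcs_sweep> subject %s: %d thresholds in [%.3f, %.3f]; best Tri %.3f (accuracy %.3f)\n",
              x$subject_id, length(x$grid), min(x$grid), max(x$grid),
              x$best_tri, x$best_accuracy))
  invisible(x)
}

#' General optimal threshold value (GOTV) summary
#'
#' Mean and sample (n-1) standard deviation of the per-subject optimal
#' thresholds. For a single subject the sd is reported as 0 with a warning.
#' Reported values are conventionally rounded to 2 (mean) and 3 (sd)
#' decimals; the unrounded values are also kept.
#'
#' @param best_tris numeric vector of per-subject optimal thresholds.
#' @return A `kfcs_gotv`: fields `thresholds`, `mean`, `sd`, `mean_rounded`,
#'   `sd_rounded`.
#' @export
gotv_summary <- function(best_tris) {
  best_tris <- as.numeric(best_tris)
  if (length(best_tris) == 0L) stop("empty threshold list")
  m <- mean(best_tris)
  if (length(best_tris) == 1L) {
    warning("single subject: standard deviation undefined, reported as 0")
    s <- 0
  } else {
    s <- stats::sd(best_tris)
  }
  structure(list(thresholds = best_tris, mean = m, sd = s,
                 mean_rounded = round(m, 2), sd_rounded = round(s, 3)),
            class = "kfcs_gotv")
}

#' @export
print.kfcs_gotv <- function(x, ...) {
  cat(sprintf("<kfcs_gotv> %d subjects: mean %.2f, sd %.3f\n",
              length(x$thresholds), x$mean_rounded, x$sd_rounded))
  invisible(x)
}

#' K-nearest-neighbour channel groups from a montage
#'
#' Group `M_i` is channel `i` plus its `k` nearest channels by Euclidean
#' montage distance; distance ties break toward the lowest channel index, so
#' the grouping is deterministic and invariant to uniform montage scaling.
#'
#' @param montage a `kfcs_montage` from [load_montage()] (or a data.frame
#'   with `label`, `x`, `y`).
#' @param k neighbours per group, `0 <= k < n`.
#' @param channels optional channel subset/order; defaults to montage order.
#' @return Named list of integer index vectors `M_i` (center first).
#' @export
knn_channel_groups <- function(montage, k, channels = NULL) {
  if (is.null(channels)) channels <- montage$label
  idx <- match(channels, montage$label)
  if (anyNA(idx)) stop("montage missing channels: ",
                       paste(channels[is.na(idx)], collapse = ", "))
  n <- length(channels)
  if (k >= n) stop("k must be smaller than the number of channels")
  xy <- cbind(montage$x[idx], montage$y[idx])
  D <- as.matrix(stats::dist(xy))
  groups <- vector("list", n)
  names(groups) <- channels
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(D[i, others], others)]  # distance, then index
    groups[[i]] <- c(i, ord[seq_len(k)])
  }
  groups
}

#' Greedy LOOCV core-node selection
#'
#' Ranks the channel groups by the LOOCV accuracy of the SVM restricted to
#' each group's feature columns (ties toward the lower center index), then
#' greedily accumulates groups: a group is kept when adding its columns
#' improves the accumulated LOOCV accuracy, and accumulation stops at the
#' first non-improvement. Returns the centers of the accumulated groups —
#' the core channels that substitute the full channel set downstream.
#'
#' @param features a [feature_table()].
#' @param groups list of index vectors from [knn_channel_groups()]
#'   (center first in each).
#' @param seed recorded for provenance; LOOCV itself is deterministic.
#' @return A `kfcs_core`: fields `centers` (ordered integer vector),
#'   `columns` (union of selected groups), `accuracy` (final LOOCV),
#'   `group_accuracy` (per-group LOOCV, ranking order).
#' @export
select_core_nodes <- function(features, groups, seed = 1) {
  ft <- as_feature_table(features)
  if (length(groups) == 0L || any(lengths(groups) == 0L)) stop("empty groups")
  groups <- lapply(groups, as.integer)
  covered <- sort(unique(unlist(groups)))
  if (!all(seq_len(ncol(ft$X)) %in% covered)) {
    stop("groups must cover all channels")
  }
  g_acc <- vapply(groups, function(g) {
    loocv_score(feature_table(ft$X[, g, drop = FALSE], ft$labels))
  }, numeric(1))
  centers_all <- vapply(groups, `[`, integer(1), 1L)
  ord <- order(-g_acc, centers_all)
  sel_centers <- centers_all[ord[1]]
  sel_cols <- sort(unique(groups[[ord[1]]]))
  best_acc <- loocv_score(feature_table(ft$X[, sel_cols, drop = FALSE], ft$labels))
  for (idx in ord[-1]) {
    cand_cols <- sort(unique(c(sel_cols, groups[[idx]])))
    acc <- loocv_score(feature_table(ft$X[, cand_cols, drop = FALSE], ft$labels))
    if (acc > best_acc) {
      best_acc <- acc
      sel_cols <- cand_cols
      sel_centers <- c(sel_centers, centers_all[idx])
    } else {
      break
    }
  }
  structure(list(centers = sel_centers, columns = sel_cols,
                 accuracy = best_acc,
                 group_accuracy = g_acc[ord], seed = seed),
            class = "kfcs_core")
}

#' Run the full detection pipeline over a cohort
#'
#' Orchestrates, per subject: band-pass preprocessing (when given continuous
#' recordings), CsEn connectivity, the threshold sweep, then cohort-level
#' GOTV, and finally per-subject core-node selection at the subject-adaptive
#' threshold — the subject's best grid point within one reported sd of the
#' GOTV — and a k-fold accuracy restricted to the selected core channels.
#' Deterministic given `seed`.
#'
#' @param subjects named list; each element either a [epoch_set()] or a
#'   list `list(recording = , events = )`.
#' @param montage a `kfcs_montage`; `NULL` skips core-node selection.
#' @param params a [csen_params()].
#' @param grid_size,folds,rule,normalize sweep controls (see
#'   [threshold_sweep()]).
#' @param knn_k neighbours per channel group (default 3).
#' @param band band-pass edges applied to continuous recordings.
#' @param seed master seed; per-subject seeds are derived from it.
#' @return A `kfcs_result`: fields `sweeps`, `gotv`, `adaptive_tri`,
#'   `core`, `final_accuracy`, `baseline_accuracy` (all-channel accuracy at
#'   the adaptive threshold).
#' @export
run_kfcs <- function(subjects, montage = NULL, params = csen_params(),
                     grid_size = 50, folds = 10, rule = "ge",
                     normalize = TRUE, knn_k = 3, band = c(0.5, 45),
                     seed = 1) {
  stopifnot(length(subjects) >= 1L)
  if (is.null(names(subjects))) names(subjects) <- sprintf("S%d", seq_along(subjects))
  conns <- list(); labels <- list()
  for (s in names(subjects)) {
    sub <- subjects[[s]]
    if (inherits(sub, "kfcs_epochs")) {
      es <- sub
    } else {
      rec <- bandpass(sub$recording, band[1], band[2])
      es <- extract_epochs(rec, sub$events, subject_id = s)
    }
    conns[[s]] <- epoch_connectivity(es, params, normalize)
    labels[[s]] <- es$labels
  }
  sweeps <- list()
  for (i in seq_along(conns)) {
    s <- names(conns)[i]
    sweeps[[s]] <- threshold_sweep(conns = conns[[s]], labels = labels[[s]],
                                   grid_size = grid_size, folds = folds,
                                   seed = seed + i, rule = rule)
    sweeps[[s]]$subject_id <- s
  }
  gotv <- gotv_summary(vapply(sweeps, `[[`, numeric(1), "best_tri"))
  adaptive <- list(); core <- list()
  final_acc <- baseline_acc <- numeric(length(conns))
  names(final_acc) <- names(baseline_acc) <- names(conns)
  for (i in seq_along(conns)) {
    s <- names(conns)[i]
    grid <- sweeps[[s]]$grid
    in_win <- which(abs(grid - gotv$mean) <= gotv$sd)
    if (length(in_win) == 0L) in_win <- which.min(abs(grid - gotv$mean))
    tri <- grid[in_win[which.max(sweeps[[s]]$accuracy[in_win])]]
    adaptive[[s]] <- tri
    ft <- features_at_threshold(conns[[s]], labels[[s]], tri, rule, s)
    baseline_acc[s] <- train_and_score(ft, folds = folds, seed = seed + 100L + i)
    if (!is.null(montage)) {
      groups <- knn_channel_groups(montage, knn_k,
                                   channels = colnames(ft$X))
      core[[s]] <- select_core_nodes(ft, groups, seed = seed + 200L + i)
      ft_core <- feature_table(ft$X[, core[[s]]$columns, drop = FALSE],
                               ft$labels, s)
      final_acc[s] <- train_and_score(ft_core, folds = folds,
                                      seed = seed + 100L + i)
    } else {
      final_acc[s] <- baseline_acc[s]
    }
  }
  structure(list(sweeps = sweeps, gotv = gotv,
                 adaptive_tri = unlist(adaptive), core = core,
                 final_accuracy = final_acc,
                 baseline_accuracy = baseline_acc, seed = seed),
            class = "kfcs_result")
}

#' @export
print.kfcs_result <- function(x, ...) {
  cat(sprintf("<kfcs_result> %d subjects; GOTV %.2f (sd %.3f); mean final accuracy %.3f\n",
              length(x$sweeps), x$gotv$mean_rounded, x$gotv$sd_rounded,
              mean(x$final_accuracy)))
  invisible(x)
}
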