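# RBF-kernel support vector machine, least-squares formulation (Suykens &
# Vandewalle 1999). Chosen because it trains by a single linear solve —
# deterministic and dependency-free — while keeping the RBF-SVM decision
# function the pipeline contract asks for. C is the regularization trade-off;
# gamma defaults to 1 / n_features on standardized features.

rbf_kernel <- function(X, Z, gamma) {
  # exp(-gamma * ||x - z||^2), rows of X vs rows of Z
  d2 <- outer(rowSums(X^2), rowSums(Z^2), `+`) - 2 * tcrossprod(X, Z)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

svm_fit <- function(X, y, C = 1, gamma = NULL) {
  # y in {-1, +1}; features standardized by the caller
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(gamma)) gamma <- 1 / max(1L, ncol(X))
  K <- rbf_kernel(X, X, gamma)
  # LS-SVM dual with bias: [[0, 1'], [1, K + I/C]] [b; alpha] = [0; y]
  M <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / C))
  sol <- solve(M, c(0, y))
  list(b = sol[1], alpha = sol[-1], X = X, gamma = gamma)
}

svm_predict <- function(fit, Xnew) {
  Xnew <- as.matrix(Xnew)
  f <- rbf_kernel(Xnew, fit$X, fit$gamma) %*% fit$alpha + fit$b
  ifelse(as.numeric(f) >= 0, 1, -1)
}

standardizer <- function(Xtrain) {
  mu <- colMeans(Xtrain)
  sdv <- apply(Xtrain, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  function(X) sweep(sweep(as.matrix(X), 2L, mu), 2L, sdv, `/`)
}

labels_to_pm1 <- function(labels) {
  ifelse(labels == "braking", 1, -1)
}

stratified_folds <- function(labels, folds, seed) {
  # deterministic stratified assignment; class ratios differ by <= 1 per fold
  fold_id <- integer(length(labels))
  rng <- make_rng(seed)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < folds) {
      stop("class '", cl, "' has fewer epochs (", length(idx),
           ") than folds (", folds, ")")
    }
    perm <- idx[rng$sample(length(idx))]
    fold_id[perm] <- rep(seq_len(folds), length.out = length(perm))
  }
  fold_id
}

# Local RNG so seeded operations never disturb the caller's RNG state.
make_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  env$with <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    })
    force(expr)
  }
  env$sample <- function(n) env$with(sample.int(n))
  env$rnorm <- function(n, sd = 1) env$with(stats::rnorm(n, sd = sd))
  env
}

#' Cross-validated SVM accuracy of a feature table
#'
#' Stratified k-fold cross-validation of an RBF-kernel SVM. Features are
#' standardized using each training fold's statistics; fold assignment is
#' seeded and deterministic.
#'
#' @param features a [feature_table()] or a plain numeric matrix
#'   (epochs x channels) with a `labels` attribute or `labels` argument.
#' @param folds number of folds (default 10).
#' @param seed integer RNG seed for fold assignment.
#' @param labels optional label vector when `features` is a bare matrix.
#' @param C,gamma SVM hyperparameters; `gamma = NULL` means `1 / n_features`.
#' @return Overall accuracy in `[0, 1]` (pooled over folds).
#' @export
train_and_score <- function(features, folds = 10, seed = 1, labels = NULL,
                            C = 1, gamma = NULL) {
  ft <- as_feature_table(features, labels)
  X <- ft$X; y <- labels_to_pm1(ft$labels)
  fold_id <- stratified_folds(ft$labels, folds, seed)
  correct <- 0L
  for (f in seq_len(folds)) {
    tr <- fold_id != f; te <- !tr
    std <- standardizer(X[tr, , drop = FALSE])
    fit <- svm_fit(std(X[tr, , drop = FALSE]), y[tr], C = C, gamma = gamma)
    pred <- svm_predict(fit, std(X[te, , drop = FALSE]))
    correct <- correct + sum(pred == y[te])
  }
  correct / length(y)
}

#' Leave-one-out cross-validated SVM accuracy
#'
#' @inheritParams train_and_score
#' @return Accuracy in `[0, 1]`.
#' @export
loocv_score <- function(features, labels = NULL, C = 1, gamma = NULL) {
  ft <- as_feature_table(features, labels)
  X <- ft$X; y <- labels_to_pm1(ft$labels)
  n <- nrow(X)
  correct <- 0L
  for (i in seq_len(n)) {
    tr <- seq_len(n) != i
    std <- standardizer(X[tr, , drop = FALSE])
    fit <- svm_fit(std(X[tr, , drop = FALSE]), y[tr], C = C, gamma = gamma)
    if (svm_predict(fit, std(X[i, , drop = FALSE])) == y[i]) correct <- correct + 1L
  }
  correct / n
}

#' Feature table: epochs x channels importance features with labels
#'
#' @param X numeric matrix, rows = epochs, columns = channels.
#' @param labels one label per row, `"braking"` or `"normal"`.
#' @param subject_id subject identifier.
#' @return A `kfcs_features` object.
#' @export
feature_table <- function(X, labels, subject_id = "S1") {
  X <- as.matrix(X)
  labels <- as.character(labels)
  if (nrow(X) != length(labels)) stop("one label per row required")
  if (anyNA(X)) stop("feature table contains missing values")
  if (!all(labels %in% c("braking", "normal"))) {
    stop("labels must be 'braking' or 'normal'")
  }
  structure(list(X = X, labels = labels, subject_id = subject_id),
            class = "kfcs_features")
}

as_feature_table <- function(features, labels = NULL) {
  if (inherits(features, "kfcs_features")) return(features)
  if (is.null(labels)) labels <- attr(features, "labels")
  if (is.null(labels)) stop("labels required for a bare feature matrix")
  feature_table(features, labels)
}

#' Two-sided binomial chance band around 0.5
#'
#' Normal-approximation band for the accuracy of a chance-level classifier on
#' `n` epochs. With `n_tests > 1` a Sidak correction widens the band, the
#' a-priori reference for the maximum over a threshold sweep.
#'
#' @param n number of epochs scored.
#' @param level coverage (default 0.95).
#' @param n_tests number of comparisons the band must cover jointly.
#' @return `c(lower, upper)`.
#' @export
chance_band <- function(n, level = 0.95, n_tests = 1) {
  alpha <- 1 - level^(1 / n_tests)
  half <- stats::qnorm(1 - alpha / 2) * sqrt(0.25 / n)
  c(max(0, 0.5 - half), min(1, 0.5 + half))
}
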