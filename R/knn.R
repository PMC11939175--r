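# k-nearest-neighbor engine under cityblock (L1) distance, with per-fold
# train-only standardization. This is the wrapped evaluator inside the CWINCA
# size sweep, so it is written here rather than delegated: the selection loop
# needs cityblock distance, standardization fitted on the training fold only,
# and deterministic tie-breaking, as one unit.

# Standardize columns by train-fold mean/sd; constant columns are left
# centered only (scale 1) rather than dividing by zero.
standardize_fold <- function(train_x, test_x) {
  mu <- colMeans(train_x)
  sg <- apply(train_x, 2L, sd)
  sg[!is.finite(sg) | sg <= 0] <- 1
  list(
    train = sweep(sweep(train_x, 2L, mu), 2L, sg, "/"),
    test = sweep(sweep(test_x, 2L, mu), 2L, sg, "/")
  )
}

# Predict test labels by k-NN with cityblock distance and equal vote weights.
# Distance ties resolve to the earliest training row (which.min / stable
# order); vote ties resolve to the class of the nearest member among the tied
# classes.
knn_predict <- function(train_x, train_y, test_x, k = 1L) {
  nt <- nrow(test_x)
  out <- character(nt)
  for (i in seq_len(nt)) {
    d <- colSums(abs(t(train_x) - test_x[i, ]))
    if (k == 1L) {
      out[i] <- train_y[which.min(d)]
    } else {
      nn <- order(d)[seq_len(min(k, length(d)))]
      votes <- table(train_y[nn])
      top <- names(votes)[votes == max(votes)]
      out[i] <- if (length(top) == 1L) top else train_y[nn][train_y[nn] %in% top][1L]
    }
  }
  out
}

#' Cross-validated 1-NN misclassification loss
#'
#' Misclassification rate of a k-nearest-neighbor classifier (cityblock/L1
#' distance, equal vote weights, per-fold standardization to zero mean and
#' unit variance computed on the training fold only) under seeded stratified
#' k-fold cross-validation. This is the subset evaluator driving
#' [cwinca_select()].
#'
#' @inheritParams split_features
#' @param cv_folds Number of CV folds (default 10).
#' @param knn_neighbors Number of neighbors (default 1).
#' @param seed Integer seed for the fold assignment.
#' @param fold_ids Optional explicit fold assignment (integer vector in
#'   `1..cv_folds`); overrides `seed`, letting callers evaluate several
#'   feature subsets on identical folds.
#' @return Pooled misclassification rate in `[0, 1]`.
#' @examples
#' df <- make_planted_features(n = 40, informative = 2, noise = 2,
#'                             class_sep = 3, seed = 1)
#' knn_cv_loss(df, cv_folds = 5, seed = 1)
#' @export
knn_cv_loss <- function(data, label_col = "label", cv_folds = 10L,
                        knn_neighbors = 1L, seed = 1L, fold_ids = NULL) {
  lm <- split_features(data, label_col)
  n <- nrow(lm$x)
  if (is.null(fold_ids)) {
    fold_ids <- stratified_folds(lm$y, cv_folds, seed)
  }
  stopifnot(length(fold_ids) == n)
  errors <- 0L
  for (f in sort(unique(fold_ids))) {
    te <- fold_ids == f
    sc <- standardize_fold(lm$x[!te, , drop = FALSE], lm$x[te, , drop = FALSE])
    pred <- knn_predict(sc$train, lm$y[!te], sc$test, k = knn_neighbors)
    errors <- errors + sum(pred != lm$y[te])
  }
  errors / n
}
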