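# Classifier bank: the standard model families evaluated on the selected
# features, each producing an out-of-fold prediction vector under seeded
# stratified cross-validation. Model fitting delegates to the established
# implementations (e1071, rpart, nnet, randomForest); the 1-NN kind shares
# the same cityblock engine as the selection loop, so its CV loss matches
# knn_cv_loss() on identical folds by construction.

CLASSIFIER_KINDS <- c("svm_poly", "knn", "tree", "neural_net", "logistic",
                      "ensemble_bag")

#' Specify a classifier for the cross-validated bank
#'
#' Supported kinds and their default hyperparameters:
#' * `svm_poly` — polynomial-kernel SVM, `degree = 3`, `cost = 1` (e1071).
#' * `knn` — 1-nearest-neighbor, cityblock distance, per-fold
#'   standardization (package engine; `k` overridable).
#' * `tree` — CART decision tree (rpart defaults).
#' * `neural_net` — one-hidden-layer network, `size = 100`,
#'   `decay = 1e-4`, `maxit = 200` (nnet).
#' * `logistic` — L2-penalized multinomial logistic regression,
#'   `decay = 1e-4` (nnet::multinom; handles two or more classes).
#' * `ensemble_bag` — bagged trees: randomForest with `mtry = d`
#'   (all features per split, i.e. bagging), `ntree = 30`.
#'
#' @param kind One of the kinds above.
#' @param ... Hyperparameter overrides for the chosen kind.
#' @param seed Integer seed for any stochastic fitting (weight init,
#'   bootstrap resamples).
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(kind, ..., seed = 1L) {
  if (!kind %in% CLASSIFIER_KINDS) {
    abort(sprintf("unsupported classifier kind '%s'; supported: %s",
                  kind, paste(CLASSIFIER_KINDS, collapse = ", ")))
  }
  structure(list(kind = kind, hyperparameters = list(...),
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' The default classifier bank
#'
#' One [classifier_spec()] per supported kind, with the documented defaults.
#'
#' @param seed Base seed; each member gets a distinct derived seed.
#' @return Named list of `classifier_spec`s.
#' @export
default_classifier_bank <- function(seed = 1L) {
  ks <- CLASSIFIER_KINDS
  setNames(lapply(seq_along(ks), function(i) {
    classifier_spec(ks[i], seed = derive_seed(seed, i))
  }), ks)
}

hp <- function(spec, name, default) spec$hyperparameters[[name]] %||% default

# Fit on the training fold, predict the test fold. Each branch seeds its fit
# so stochastic learners are reproducible.
fit_predict_fold <- function(spec, train_x, train_y, test_x, fold_seed) {
  yfac <- factor(train_y, levels = sort(unique(train_y)))
  tr <- as.data.frame(train_x)
  te <- as.data.frame(test_x)
  names(te) <- names(tr)
  switch(spec$kind,
    svm_poly = {
      fit <- e1071::svm(x = train_x, y = yfac, kernel = "polynomial",
                        degree = hp(spec, "degree", 3),
                        cost = hp(spec, "cost", 1), scale = FALSE)
      as.character(predict(fit, test_x))
    },
    knn = {
      sc <- standardize_fold(train_x, test_x)
      knn_predict(sc$train, train_y, sc$test, k = hp(spec, "k", 1L))
    },
    tree = {
      tr$..y <- yfac
      fit <- withr::with_seed(fold_seed, rpart::rpart(..y ~ ., data = tr, method = "class"))
      as.character(predict(fit, te, type = "class"))
    },
    neural_net = {
      fit <- withr::with_seed(fold_seed, suppressWarnings(
        nnet::nnet(x = train_x, y = nnet::class.ind(yfac),
                   size = hp(spec, "size", 100L),
                   decay = hp(spec, "decay", 1e-4),
                   maxit = hp(spec, "maxit", 200L),
                   MaxNWts = hp(spec, "MaxNWts", 1e6),
                   softmax = TRUE, trace = FALSE)
      ))
      pr <- predict(fit, test_x)
      levels(yfac)[max.col(pr, ties.method = "first")]
    },
    logistic = {
      tr$..y <- yfac
      fit <- withr::with_seed(fold_seed, suppressWarnings(
        nnet::multinom(..y ~ ., data = tr, decay = hp(spec, "decay", 1e-4),
                       maxit = hp(spec, "maxit", 200L), MaxNWts = 1e6,
                       trace = FALSE)
      ))
      as.character(predict(fit, te))
    },
    ensemble_bag = {
      fit <- withr::with_seed(fold_seed, randomForest::randomForest(
        x = train_x, y = yfac,
        ntree = hp(spec, "ntree", 30L),
        mtry = hp(spec, "mtry", ncol(train_x))
      ))
      as.character(predict(fit, test_x))
    }
  )
}

#' Out-of-fold prediction vector for one classifier
#'
#' Trains the specified classifier on each training fold and predicts the
#' held-out fold, yielding one out-of-fold predicted label per sample — the
#' prediction vector fused by [ihmv()]. Fold assignment is seeded and
#' stratified; stochastic learners are seeded per fold from `spec$seed`.
#' Out-of-fold (rather than refit-on-all) predictions are used because only
#' they carry honest accuracies for ensemble ranking.
#'
#' @inheritParams split_features
#' @param spec A [classifier_spec()].
#' @param folds Number of CV folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param fold_ids Optional explicit fold assignment, overriding `seed`.
#' @return An object of class `cv_predictions`: `model_name`, `predicted`
#'   (character vector, length n), `truth`, `accuracy`, `folds`, `fold_ids`.
#' @examples
#' df <- make_planted_features(n = 60, informative = 2, noise = 2,
#'                             class_sep = 3, seed = 1)
#' crossval_predictions(df, classifier_spec("svm_poly"), folds = 5)
#' @export
crossval_predictions <- function(data, spec, label_col = "label", folds = 10L,
                                 seed = 1L, fold_ids = NULL) {
  stopifnot(inherits(spec, "classifier_spec"))
  lm <- split_features(data, label_col)
  n <- nrow(lm$x)
  if (n < folds) abort(sprintf("need n >= folds; got n = %d, folds = %d.", n, folds))
  if (is.null(fold_ids)) fold_ids <- stratified_folds(lm$y, folds, seed)
  predicted <- character(n)
  for (f in sort(unique(fold_ids))) {
    te <- fold_ids == f
    predicted[te] <- fit_predict_fold(
      spec, lm$x[!te, , drop = FALSE], lm$y[!te], lm$x[te, , drop = FALSE],
      fold_seed = derive_seed(spec$seed, f)
    )
  }
  structure(
    list(model_name = spec$kind, predicted = predicted, truth = lm$y,
         accuracy = mean(predicted == lm$y), folds = as.integer(folds),
         fold_ids = fold_ids),
    class = "cv_predictions"
  )
}

#' @export
print.cv_predictions <- function(x, ...) {
  cat(sprintf("<cv_predictions> %s: %d-fold out-of-fold accuracy %.4f (n = %d)\n",
              x$model_name, x$folds, x$accuracy, length(x$truth)))
  invisible(x)
}

#' Pool cross-validated prediction vectors into a prediction set
#'
#' @param cvs Named list of [crossval_predictions()] results sharing truth.
#' @return A [prediction_set()].
#' @export
bind_cv_predictions <- function(cvs) {
  stopifnot(length(cvs) >= 1L)
  truth <- cvs[[1L]]$truth
  for (cv in cvs) {
    if (!identical(cv$truth, truth)) abort("cv_predictions disagree on truth.")
  }
  nms <- names(cvs) %||% vapply(cvs, `[[`, character(1), "model_name")
  df <- as_tibble(setNames(lapply(cvs, `[[`, "predicted"), nms))
  prediction_set(df, truth = truth)
}
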