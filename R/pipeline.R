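# End-to-end orchestration: per-feature-set CWINCA selection, the
# cross-validated classifier bank, pooling of all out-of-fold prediction
# vectors, IHMV fusion, and metrics reporting.

#' Run the full selection / classification / voting pipeline
#'
#' For every named feature set — and, when there are several, their
#' column-wise concatenation as an additional `"combined"` set — the pipeline
#' (1) runs [cwinca_select()], (2) computes out-of-fold prediction vectors for
#' each configured classifier on the selected features, (3) pools every
#' prediction vector into one [prediction_set()], (4) fuses them with
#' [ihmv()], and (5) reports per-model and final voted metrics. Fully
#' reproducible from the configuration seeds.
#'
#' By default selection is performed once on the full data and classifiers
#' are then cross-validated on the selected columns. Setting `nested = TRUE`
#' instead re-runs selection inside each training fold before predicting the
#' held-out fold, which removes the selection bias of the default order at
#' extra cost.
#'
#' @param feature_sets Named list of labeled feature data frames sharing the
#'   same label vector.
#' @param classifiers Named list of [classifier_spec()]s
#'   (default [default_classifier_bank()]).
#' @param config A [cwinca_config()].
#' @param nca An [nca_config()].
#' @param label_col Label column name (default `"label"`).
#' @param folds CV folds for the classifier bank (default 10).
#' @param seed Seed for the classifier-bank fold assignment.
#' @param combine Whether to add the concatenated `"combined"` set
#'   (default TRUE when more than one set is given).
#' @param nested Re-run selection inside each training fold (default FALSE,
#'   which mirrors the select-then-cross-validate order).
#' @return An object of class `pipeline_report`: `selection` (named list of
#'   `cwinca_trace`s), `model_metrics` (tibble: feature_set, classifier,
#'   accuracy, macro_f1), `predictions` (the pooled `prediction_set`),
#'   `voted` (the `voted_result`), `final_metrics` (a `metrics_report`), and
#'   `seeds`.
#' @examples
#' \donttest{
#' corpus <- make_text_corpus(n = 60, classes = 2, seed = 1)
#' sets <- list(h16 = embed_texts(corpus, hashing_backend(16)))
#' run_pipeline(sets, classifiers = list(knn = classifier_spec("knn")),
#'              config = cwinca_config(cv_folds = 5), folds = 5)
#' }
#' @export
run_pipeline <- function(feature_sets, classifiers = default_classifier_bank(),
                         config = cwinca_config(), nca = nca_config(),
                         label_col = "label", folds = 10L, seed = 1L,
                         combine = length(feature_sets) > 1L, nested = FALSE) {
  if (!is.list(feature_sets) || length(feature_sets) < 1L) {
    abort("`feature_sets` must be a non-empty named list of data frames.")
  }
  if (is.null(names(feature_sets)) || any(!nzchar(names(feature_sets)))) {
    abort("`feature_sets` must be named.")
  }
  sets <- feature_sets
  if (combine && length(feature_sets) > 1L) {
    sets$combined <- concat_features(feature_sets, label_col = label_col)
  }

  selection <- list()
  cvs <- list()
  cv_meta <- list()
  for (set_name in names(sets)) {
    data <- sets[[set_name]]
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e) {
        abort(sprintf("[%s / %s] %s", set_name, what, conditionMessage(e)))
      })
    }
    trace <- stage("cwinca_select",
                   cwinca_select(data, config = config, nca = nca,
                                 label_col = label_col))
    selection[[set_name]] <- trace
    for (cl_name in names(classifiers)) {
      spec <- classifiers[[cl_name]]
      id <- paste(set_name, cl_name, sep = "_")
      cvs[[id]] <- if (nested) {
        stage(cl_name, nested_crossval(data, spec, config, nca, label_col,
                                       folds, seed))
      } else {
        stage(cl_name, crossval_predictions(trace$selected_data, spec,
                                            label_col = label_col,
                                            folds = folds, seed = seed))
      }
      cv_meta[[id]] <- c(set = set_name, classifier = cl_name)
    }
  }

  pset <- bind_cv_predictions(cvs)
  voted <- ihmv(pset)
  final <- compute_metrics(pset$truth, voted$voted_labels)

  model_metrics <- purrr::map_dfr(names(cvs), function(id) {
    cv <- cvs[[id]]
    mr <- suppressWarnings(compute_metrics(cv$truth, cv$predicted))
    tibble(feature_set = cv_meta[[id]][["set"]],
           classifier = cv_meta[[id]][["classifier"]],
           accuracy = mr$accuracy, macro_f1 = mr$macro$f1)
  })

  structure(
    list(selection = selection, model_metrics = model_metrics,
         predictions = pset, voted = voted, final_metrics = final,
         seeds = list(pipeline = seed, cwinca = config$seed, nca = nca$seed),
         nested = nested),
    class = "pipeline_report"
  )
}

# Leakage-safe variant: CWINCA selection re-run on each training fold; the
# held-out fold is predicted on that fold's selected features.
nested_crossval <- function(data, spec, config, nca, label_col, folds, seed) {
  lm <- split_features(data, label_col)
  n <- nrow(lm$x)
  fold_ids <- stratified_folds(lm$y, folds, seed)
  predicted <- character(n)
  for (f in sort(unique(fold_ids))) {
    te <- fold_ids == f
    train <- data[!te, , drop = FALSE]
    trace <- cwinca_select(train, config = config, nca = nca,
                           label_col = label_col)
    keep <- as.character(trace$selected_features)
    # normalize the held-out rows with the training-fold min-max mapping
    tr_norm <- trace$selected_data
    lo <- vapply(keep, function(cn) min(train[[cn]]), numeric(1))
    rg <- vapply(keep, function(cn) max(train[[cn]]), numeric(1)) - lo + config$epsilon
    te_x <- sweep(sweep(as.matrix(data[te, keep, drop = FALSE]), 2L, lo), 2L, rg, "/")
    predicted[te] <- fit_predict_fold(
      spec, as.matrix(tr_norm[keep]), lm$y[!te], te_x,
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
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d feature set(s), %d prediction vector(s)\n",
              length(x$selection), length(x$predictions$model_names)))
  cat(sprintf("voted: ensemble of %d, accuracy %.2f%% | macro F1 %.2f%%\n",
              x$voted$ensemble_size, 100 * x$voted$accuracy,
              x$final_metrics$macro$f1))
  invisible(x)
}

#' @rdname run_pipeline
#' @param x,object A `pipeline_report`.
#' @param ... Unused.
#' @export
tidy.pipeline_report <- function(x, ...) {
  x$model_metrics
}

#' @rdname run_pipeline
#' @export
glance.pipeline_report <- function(x, ...) {
  tibble(n_feature_sets = length(x$selection),
         n_models = length(x$predictions$model_names),
         ensemble_size = x$voted$ensemble_size,
         voted_accuracy = x$final_metrics$accuracy,
         macro_f1 = x$final_metrics$macro$f1)
}

#' @rdname run_pipeline
#' @export
autoplot.pipeline_report <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$classifier, y = .data$accuracy,
                                   fill = .data$feature_set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = object$final_metrics$accuracy,
                        linetype = "dashed") +
    ggplot2::labs(y = "out-of-fold accuracy (%)", x = NULL,
                  caption = "dashed line: final voted accuracy")
}

#' Serialize a pipeline report as canonical JSON
#'
#' Produces a deterministic JSON rendering of the full report (selection
#' traces, per-model metrics, per-k voting sweep, confusion matrix). Reruns
#' with identical configuration yield byte-identical output.
#'
#' @param report A `pipeline_report`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "pipeline_report"))
  obj <- list(
    selection = lapply(report$selection, function(tr) list(
      ranked_features = as.character(tr$ranked_features),
      cumulative_weights = tr$cumulative_weights,
      start_size = tr$start_size, stop_size = tr$stop_size,
      losses = tr$losses, best_loss = tr$best_loss,
      chosen_size = tr$chosen_size,
      selected_features = as.character(tr$selected_features)
    )),
    model_metrics = report$model_metrics,
    voted = list(ensemble_size = report$voted$ensemble_size,
                 ensemble_members = report$voted$ensemble_members,
                 accuracy = report$voted$accuracy,
                 per_k = report$voted$per_k),
    final = list(accuracy = report$final_metrics$accuracy,
                 macro = report$final_metrics$macro,
                 per_class = report$final_metrics$per_class,
                 confusion = report$final_metrics$confusion),
    seeds = report$seeds,
    nested = report$nested
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}
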