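# Iterative hybrid majority voting (IHMV): sort model prediction vectors by
# accuracy, mode-vote the top-k for k = 3..m, and keep the voted labeling with
# the highest accuracy (smallest k on ties).

#' Bundle prediction vectors into a prediction set
#'
#' @param predictions A data frame with one column per model (each column a
#'   prediction vector: one predicted label per sample). May contain the truth
#'   column, named by `truth_col`.
#' @param truth Optional explicit truth vector; overrides `truth_col`.
#' @param truth_col Name of the truth column inside `predictions`
#'   (default `"truth"`).
#' @return An object of class `prediction_set`: `predictions` (n x m character
#'   matrix), `truth`, `model_names`, `accuracies` (fraction of each model's
#'   predictions matching truth).
#' @examples
#' df <- tibble::tibble(m1 = c("a", "b"), m2 = c("a", "a"), truth = c("a", "b"))
#' prediction_set(df)
#' @export
prediction_set <- function(predictions, truth = NULL, truth_col = "truth") {
  if (!is.data.frame(predictions)) abort("`predictions` must be a data frame.")
  if (is.null(truth)) {
    if (!truth_col %in% names(predictions)) {
      abort(sprintf("truth column '%s' not found and no `truth` given.", truth_col))
    }
    truth <- predictions[[truth_col]]
    predictions <- predictions[setdiff(names(predictions), truth_col)]
  }
  truth <- as.character(truth)
  if (ncol(predictions) < 1L) abort("need at least one model column.")
  if (nrow(predictions) != length(truth)) {
    abort(sprintf("predictions have %d rows but truth has %d entries.",
                  nrow(predictions), length(truth)))
  }
  pm <- as.matrix(as.data.frame(lapply(predictions, as.character)))
  colnames(pm) <- names(predictions)
  acc <- colMeans(pm == truth)
  structure(
    list(predictions = pm, truth = truth,
         model_names = colnames(pm), accuracies = unname(acc)),
    class = "prediction_set"
  )
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("<prediction_set> %d models x %d samples; accuracies %s\n",
              length(x$model_names), length(x$truth),
              paste(sprintf("%.3f", x$accuracies), collapse = ", ")))
  invisible(x)
}

#' Majority vote over a ranked set of prediction vectors
#'
#' Per sample, returns the most frequent label among the model columns. On a
#' tie, the vote of the best-ranked model that voted for one of the tied
#' labels wins; any residual tie falls to the smallest label in canonical
#' (sorted) order. Columns are taken as already ranked best-first unless
#' `ranking` reorders them.
#'
#' @param predictions A data frame or character matrix, one column per model,
#'   one row per sample.
#' @param ranking Optional integer permutation of the columns, best model
#'   first.
#' @return Character vector of voted labels, length n.
#' @examples
#' mode_vote(data.frame(m1 = "a", m2 = "a", m3 = "b"))
#' @export
mode_vote <- function(predictions, ranking = NULL) {
  pm <- if (is.matrix(predictions)) predictions else
    as.matrix(as.data.frame(lapply(predictions, as.character)))
  if (length(pm) == 0L || ncol(pm) < 1L) abort("`predictions` must have at least one model column.")
  if (!is.null(ranking)) pm <- pm[, ranking, drop = FALSE]
  lvls <- sort(unique(as.vector(pm)))
  counts <- vapply(lvls, function(l) rowSums(pm == l), numeric(nrow(pm)))
  counts <- matrix(counts, nrow = nrow(pm), dimnames = list(NULL, lvls))
  top <- max.col(counts, ties.method = "first")
  out <- lvls[top]
  maxc <- counts[cbind(seq_len(nrow(pm)), top)]
  tied_rows <- which(rowSums(counts == maxc) > 1L)
  for (i in tied_rows) {
    tied <- lvls[counts[i, ] == maxc[i]]
    votes <- pm[i, ]
    hit <- votes[votes %in% tied][1L] # best-ranked model voting a tied label
    out[i] <- if (is.na(hit)) tied[1L] else hit
  }
  out
}

#' Iterative hybrid majority voting
#'
#' Sorts the models of a [prediction_set()] by descending accuracy (ties keep
#' original order), mode-votes the top-k for every k from 3 to m (k = m alone
#' when m < 3), and returns the voted labeling with maximal accuracy against
#' truth, preferring the smallest k on ties. Because k = m is always
#' evaluated, the result's accuracy is at least that of the plain all-model
#' majority vote.
#'
#' For deployment with truth unavailable, freeze the `ensemble_size` chosen
#' during a calibration run and apply [mode_vote()] to the top-k columns.
#'
#' @param pset A `prediction_set`.
#' @return An object of class `voted_result`: `voted_labels`,
#'   `ensemble_size`, `ensemble_members`, `accuracy`, and `per_k` (a tibble of
#'   every evaluated k with its accuracy).
#' @examples
#' ps <- make_prediction_ensemble(n = 200, model_accuracies = rep(0.7, 5),
#'                                classes = 2, seed = 1)
#' ihmv(ps)
#' @export
ihmv <- function(pset) {
  stopifnot(inherits(pset, "prediction_set"))
  m <- length(pset$model_names)
  ord <- order(-pset$accuracies, seq_len(m))
  ranked <- pset$predictions[, ord, drop = FALSE]
  ks <- if (m < 3L) m else seq.int(3L, m)
  votes <- lapply(ks, function(k) mode_vote(ranked[, seq_len(k), drop = FALSE]))
  accs <- vapply(votes, function(v) mean(v == pset$truth), numeric(1))
  best <- which.max(accs) # first maximum = smallest k on ties
  structure(
    list(voted_labels = votes[[best]],
         ensemble_size = as.integer(ks[best]),
         ensemble_members = pset$model_names[ord][seq_len(ks[best])],
         accuracy = accs[best],
         per_k = tibble(k = as.integer(ks), accuracy = accs)),
    class = "voted_result"
  )
}

#' @export
print.voted_result <- function(x, ...) {
  cat(sprintf("<voted_result> ensemble of %d models, accuracy %.4f\n",
              x$ensemble_size, x$accuracy))
  invisible(x)
}

#' @rdname ihmv
#' @param x,object A `voted_result`.
#' @param ... Unused.
#' @export
tidy.voted_result <- function(x, ...) {
  dplyr::mutate(x$per_k, chosen = .data$k == x$ensemble_size)
}

#' @rdname ihmv
#' @export
glance.voted_result <- function(x, ...) {
  tibble(ensemble_size = x$ensemble_size, accuracy = x$accuracy,
         k_evaluated = nrow(x$per_k))
}

#' @rdname ihmv
#' @export
autoplot.voted_result <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$k, y = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = td[td$chosen, ], colour = "red", size = 2) +
    ggplot2::labs(x = "ensemble size k (accuracy-ranked models)",
                  y = "voted accuracy")
}

#' Serialize a voted result as JSON
#'
#' @param voted A `voted_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_voted_json <- function(voted, path) {
  stopifnot(inherits(voted, "voted_result"))
  obj <- list(
    voted_labels = voted$voted_labels,
    ensemble_size = voted$ensemble_size,
    ensemble_members = voted$ensemble_members,
    accuracy = voted$accuracy,
    per_k_accuracies = as.list(setNames(voted$per_k$accuracy,
                                        paste0("k", voted$per_k$k)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
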