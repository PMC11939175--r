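# Classification metrics: confusion matrix, per-class and macro-averaged
# precision/recall/F1, all reported as percentages.

#' Confusion matrix and macro-averaged classification metrics
#'
#' Builds the confusion matrix (rows = true class, columns = predicted class,
#' over the union of both label alphabets in canonical sorted order) and
#' derives per-class precision `100*TP/(TP+FP)`, recall `100*TP/(TP+FN)` and
#' F1 (harmonic mean), plus their unweighted macro averages and overall
#' accuracy. A class never predicted has undefined precision; it is reported
#' as 0 with a warning (likewise recall for a class absent from truth, and F1
#' when precision + recall is 0).
#'
#' @param truth Vector of true labels, length n.
#' @param predicted Vector of predicted labels, length n.
#' @return An object of class `metrics_report`: `confusion` (c x c integer
#'   matrix), `accuracy` (percent), `per_class` (tibble of class, precision,
#'   recall, f1, support), `macro` (one-row tibble of macro precision /
#'   recall / f1).
#' @examples
#' compute_metrics(c("a", "a", "b"), c("a", "b", "b"))
#' @export
compute_metrics <- function(truth, predicted) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    abort(sprintf("length mismatch: truth has %d entries, predicted has %d.",
                  length(truth), length(predicted)))
  }
  lvls <- label_alphabet(truth, predicted)
  conf <- table(factor(truth, levels = lvls), factor(predicted, levels = lvls))
  conf <- matrix(as.integer(conf), nrow = length(lvls),
                 dimnames = list(true = lvls, predicted = lvls))
  tp <- diag(conf)
  fp <- colSums(conf) - tp
  fn <- rowSums(conf) - tp

  undefined <- lvls[(tp + fp) == 0 | (tp + fn) == 0]
  if (length(undefined) > 0L) {
    warn(sprintf("class(es) %s absent from predictions or truth; undefined metrics reported as 0.",
                 paste(undefined, collapse = ", ")))
  }
  safe_pct <- function(num, den) ifelse(den > 0, 100 * num / den, 0)
  precision <- safe_pct(tp, tp + fp)
  recall <- safe_pct(tp, tp + fn)
  f1 <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)

  structure(
    list(confusion = conf,
         accuracy = 100 * sum(tp) / length(truth),
         per_class = tibble(class = lvls, precision = unname(precision),
                            recall = unname(recall), f1 = unname(f1),
                            support = unname(rowSums(conf))),
         macro = tibble(precision = mean(precision), recall = mean(recall),
                        f1 = mean(f1))),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> accuracy %.2f%% | macro P %.2f%% R %.2f%% F1 %.2f%%\n",
              x$accuracy, x$macro$precision, x$macro$recall, x$macro$f1))
  print(x$confusion)
  invisible(x)
}

#' @rdname compute_metrics
#' @param x,object A `metrics_report`.
#' @param ... Unused.
#' @export
tidy.metrics_report <- function(x, ...) {
  x$per_class
}

#' @rdname compute_metrics
#' @export
glance.metrics_report <- function(x, ...) {
  tibble(accuracy = x$accuracy,
         macro_precision = x$macro$precision,
         macro_recall = x$macro$recall,
         macro_f1 = x$macro$f1,
         n = sum(x$confusion))
}

#' @rdname compute_metrics
#' @export
autoplot.metrics_report <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("true", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted class", y = "true class")
}
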