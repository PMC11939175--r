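# Cumulative-weight iterative NCA (CWINCA) feature selection:
# min-max normalize, fit NCA weights, rank features by weight, bound the
# candidate subset sizes by cumulative-weight thresholds, then pick the size
# whose top-ranked subset minimizes 1-NN cross-validation loss.

#' CWINCA configuration
#'
#' @param start_threshold Cumulative-weight fraction at which the size sweep
#'   starts (default 0.5): the smallest k whose top-k ranked weights hold at
#'   least this fraction of the total weight.
#' @param stop_threshold Cumulative-weight fraction at which the sweep stops
#'   (default 0.999).
#' @param fallback_start Start size used when no rank reaches
#'   `start_threshold` (all-zero weights); clamped to d (default 10).
#' @param cv_folds Folds for the 1-NN CV evaluator (default 10).
#' @param knn_neighbors Neighbors for the evaluator (default 1).
#' @param knn_metric Distance metric; only `"cityblock"` is supported.
#' @param epsilon Positive constant added to each column's range during
#'   min-max normalization, guarding constant columns (default 1e-8).
#' @param seed Integer seed controlling the CV fold assignment.
#' @return A list of class `cwinca_config`.
#' @export
cwinca_config <- function(start_threshold = 0.5, stop_threshold = 0.999,
                          fallback_start = 10L, cv_folds = 10L,
                          knn_neighbors = 1L, knn_metric = "cityblock",
                          epsilon = 1e-8, seed = 1L) {
  if (start_threshold <= 0 || start_threshold > 1) abort("`start_threshold` must be in (0, 1].")
  if (stop_threshold <= 0 || stop_threshold > 1) abort("`stop_threshold` must be in (0, 1].")
  if (start_threshold > stop_threshold) abort("`start_threshold` must be <= `stop_threshold`.")
  if (fallback_start < 1) abort("`fallback_start` must be a positive integer.")
  if (cv_folds < 2) abort("`cv_folds` must be at least 2.")
  knn_metric <- match.arg(knn_metric, "cityblock")
  if (epsilon <= 0) abort("`epsilon` must be positive.")
  structure(
    list(start_threshold = start_threshold, stop_threshold = stop_threshold,
         fallback_start = as.integer(fallback_start),
         cv_folds = as.integer(cv_folds),
         knn_neighbors = as.integer(knn_neighbors),
         knn_metric = knn_metric, epsilon = epsilon, seed = as.integer(seed)),
    class = "cwinca_config"
  )
}

#' Min-max normalize feature columns
#'
#' Maps each feature column to `(x - min) / (max - min + epsilon)`, leaving the
#' label column untouched. Outputs lie in `[0, 1)`; constant columns map to
#' all-zeros (the epsilon in the denominator prevents 0/0).
#'
#' @inheritParams split_features
#' @param epsilon Positive constant added to the range.
#' @return A tibble with normalized feature columns and the label column.
#' @export
minmax_normalize <- function(data, epsilon = 1e-8, label_col = "label") {
  if (epsilon <= 0) abort("`epsilon` must be positive.")
  lm <- split_features(data, label_col, require_classes = 1L)
  rng_lo <- apply(lm$x, 2L, min)
  rng <- apply(lm$x, 2L, max) - rng_lo + epsilon
  xn <- sweep(sweep(lm$x, 2L, rng_lo), 2L, rng, "/")
  out <- as_tibble(as.data.frame(xn))
  names(out) <- lm$feature_names
  out[[label_col]] <- data[[label_col]]
  out
}

#' Rank features and bound the subset-size sweep by cumulative weight
#'
#' Sorts features by descending weight (ties broken by ascending original
#' position), computes the normalized cumulative weight curve, and derives the
#' start and stop subset sizes: the smallest ranks at which the curve reaches
#' `start_threshold` and `stop_threshold`. When the curve never reaches a
#' threshold (e.g. all-zero weights), the start size falls back to
#' `min(fallback_start, d)` and the stop size to `d`; the start size is
#' clamped down to the stop size if needed.
#'
#' @param weights Nonnegative numeric vector of feature weights, optionally
#'   named.
#' @param config A [cwinca_config()].
#' @return A list: `ranked_features` (names or indices in descending-weight
#'   order), `cumulative_weights`, `start_size`, `stop_size`.
#' @examples
#' cumulative_bounds(c(a = 0.4, b = 0.3, c = 0.2, d = 0.1))
#' @export
cumulative_bounds <- function(weights, config = cwinca_config()) {
  if (length(weights) < 1L) abort("`weights` must have length >= 1.")
  if (!all(is.finite(weights))) abort("`weights` must be finite.")
  if (any(weights < 0)) abort("`weights` must be nonnegative.")
  d <- length(weights)
  ids <- names(weights) %||% seq_len(d)
  ord <- order(-weights, seq_len(d))
  total <- sum(weights)
  cw <- if (total > 0) cumsum(weights[ord]) / total else rep(0, d)
  start_size <- which(cw >= config$start_threshold)[1L]
  if (is.na(start_size)) start_size <- min(config$fallback_start, d)
  stop_size <- which(cw >= config$stop_threshold)[1L]
  if (is.na(stop_size)) stop_size <- d
  if (start_size > stop_size) start_size <- stop_size
  list(ranked_features = ids[ord], cumulative_weights = unname(cw),
       start_size = as.integer(start_size), stop_size = as.integer(stop_size))
}

#' Cumulative-weight iterative NCA feature selection
#'
#' Runs the full selection pipeline: min-max normalization, NCA weight fitting,
#' cumulative-weight ranking and sweep bounds, then a 1-NN cross-validation
#' loss evaluation of every candidate subset size between the start and stop
#' bounds (each candidate is the top-s ranked features). The chosen size is the
#' first (smallest) size attaining the minimal loss. The same seeded fold
#' assignment is reused for every candidate size so losses are comparable.
#'
#' @inheritParams split_features
#' @param config A [cwinca_config()] (normalization, bounds, CV evaluator).
#' @param nca An [nca_config()] for the weight-fitting stage.
#' @return An object of class `cwinca_trace` carrying the full selection
#'   record: `ranked_features`, `cumulative_weights`, `start_size`,
#'   `stop_size`, `losses` (one per evaluated size), `best_loss`,
#'   `chosen_size`, `selected_features`, the fitted `nca` model, and
#'   `selected_data` (normalized selected columns plus label, ready for a
#'   downstream classifier).
#' @examples
#' df <- make_planted_features(n = 80, informative = 2, noise = 6,
#'                             class_sep = 2, seed = 1)
#' tr <- cwinca_select(df, config = cwinca_config(cv_folds = 5))
#' glance(tr)
#' @export
cwinca_select <- function(data, config = cwinca_config(), nca = nca_config(),
                          label_col = "label") {
  norm <- minmax_normalize(data, epsilon = config$epsilon, label_col = label_col)
  fit <- nca_fit(norm, config = nca, label_col = label_col)
  bounds <- cumulative_bounds(fit$weights, config)
  lm <- split_features(norm, label_col)
  fold_ids <- stratified_folds(lm$y, config$cv_folds, config$seed)
  sizes <- seq.int(bounds$start_size, bounds$stop_size)
  losses <- vapply(sizes, function(s) {
    keep <- bounds$ranked_features[seq_len(s)]
    sub <- norm[c(keep, label_col)]
    knn_cv_loss(sub, label_col = label_col, cv_folds = config$cv_folds,
                knn_neighbors = config$knn_neighbors, fold_ids = fold_ids)
  }, numeric(1))
  best_at <- which.min(losses) # first minimum = smallest size on ties
  chosen_size <- sizes[best_at]
  selected <- bounds$ranked_features[seq_len(chosen_size)]
  structure(
    list(ranked_features = bounds$ranked_features,
         cumulative_weights = bounds$cumulative_weights,
         start_size = bounds$start_size, stop_size = bounds$stop_size,
         losses = losses, best_loss = losses[best_at],
         chosen_size = as.integer(chosen_size),
         selected_features = selected,
         nca = fit, config = config, label_col = label_col,
         selected_data = norm[c(selected, label_col)]),
    class = "cwinca_trace"
  )
}

#' @export
print.cwinca_trace <- function(x, ...) {
  cat(sprintf(
    "<cwinca_trace> %d features -> %d selected (sweep %d..%d, best 1-NN CV loss %.4f)\n",
    length(x$ranked_features), x$chosen_size, x$start_size, x$stop_size,
    x$best_loss
  ))
  invisible(x)
}

#' @rdname cwinca_select
#' @param x,object A `cwinca_trace`.
#' @param type `"losses"` (default) for the per-size loss sweep, `"features"`
#'   for the ranked features with cumulative weights and selection flags.
#' @param ... Unused.
#' @export
tidy.cwinca_trace <- function(x, type = c("losses", "features"), ...) {
  type <- match.arg(type)
  if (type == "losses") {
    tibble(size = seq.int(x$start_size, x$stop_size), loss = x$losses,
           chosen = seq.int(x$start_size, x$stop_size) == x$chosen_size)
  } else {
    tibble(rank = seq_along(x$ranked_features),
           feature = as.character(x$ranked_features),
           cumulative_weight = x$cumulative_weights,
           selected = seq_along(x$ranked_features) <= x$chosen_size)
  }
}

#' @rdname cwinca_select
#' @export
glance.cwinca_trace <- function(x, ...) {
  tibble(n_features = length(x$ranked_features),
         start_size = x$start_size, stop_size = x$stop_size,
         chosen_size = x$chosen_size, best_loss = x$best_loss,
         nca_converged = x$nca$converged)
}

#' @rdname cwinca_select
#' @export
autoplot.cwinca_trace <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$size, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = td[td$chosen, ], colour = "red", size = 2) +
    ggplot2::labs(x = "subset size (top-ranked features)",
                  y = "1-NN CV misclassification loss")
}

#' Serialize a selection trace as JSON
#'
#' Writes the complete `cwinca_trace` record (ranked features, cumulative
#' weights, sweep bounds, per-size losses, chosen subset) with full numeric
#' precision. The normalized selected-column data are not embedded; use
#' [write_features()] on `trace$selected_data`.
#'
#' @param trace A `cwinca_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_json <- function(trace, path) {
  stopifnot(inherits(trace, "cwinca_trace"))
  obj <- list(
    ranked_features = as.character(trace$ranked_features),
    cumulative_weights = trace$cumulative_weights,
    start_size = trace$start_size, stop_size = trace$stop_size,
    losses = trace$losses, best_loss = trace$best_loss,
    chosen_size = trace$chosen_size,
    selected_features = as.character(trace$selected_features),
    nca_weights = as.list(trace$nca$weights)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
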