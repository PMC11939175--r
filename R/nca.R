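# Neighborhood component analysis in its feature-selection form: one
# nonnegative weight per feature, learned by maximizing the expected
# leave-one-out 1-NN accuracy under a softmax over weighted L1 distances,
# with an L2 penalty on the weights.
#
#   d_w(i, j) = sum_r w_r^2 |x_ir - x_jr|
#   p_ij      = exp(-d_w(i, j)) / sum_{k != i} exp(-d_w(i, k)),  p_ii = 0
#   p_i       = sum_{j : y_j = y_i, j != i} p_ij
#   F(w)      = (1/n) sum_i p_i - lambda * sum_r w_r^2
#
# Weights enter only through w^2, so the sign is immaterial; fitted models
# store the nonnegative representative.

#' NCA hyperparameter bundle
#'
#' @param lambda Nonnegative L2 penalty on the weights. `NULL` (default) means
#'   `1/n`, resolved when the data are seen.
#' @param learning_rate Positive base step size for stochastic gradient ascent;
#'   decays as `1/sqrt(epoch)`.
#' @param epochs Maximum number of passes over the samples.
#' @param tolerance Relative objective change below which (sustained over three
#'   consecutive epochs) the fit stops early.
#' @param seed Integer; fully determines the per-epoch sample visit order.
#' @return A list of class `nca_config`.
#' @export
nca_config <- function(lambda = NULL, learning_rate = 0.01, epochs = 50L,
                       tolerance = 1e-6, seed = 1L) {
  if (!is.null(lambda) && (!is.numeric(lambda) || lambda < 0)) {
    abort("`lambda` must be NULL or a nonnegative number.")
  }
  if (learning_rate <= 0) abort("`learning_rate` must be positive.")
  if (epochs < 1) abort("`epochs` must be a positive integer.")
  if (tolerance <= 0) abort("`tolerance` must be positive.")
  structure(
    list(lambda = lambda, learning_rate = learning_rate,
         epochs = as.integer(epochs), tolerance = tolerance,
         seed = as.integer(seed)),
    class = "nca_config"
  )
}

check_weights <- function(weights, d) {
  if (length(weights) != d) {
    abort(sprintf("`weights` has length %d but the data have %d features.",
                  length(weights), d))
  }
  if (!all(is.finite(weights))) abort("`weights` must be finite.")
  invisible(weights)
}

# Weighted L1 distance matrix with Inf on the diagonal.
nca_distance_matrix <- function(x, w2) {
  n <- nrow(x)
  dmat <- matrix(0, n, n)
  for (r in seq_len(ncol(x))) {
    dmat <- dmat + w2[r] * abs(outer(x[, r], x[, r], "-"))
  }
  diag(dmat) <- Inf
  dmat
}

# Softmax neighbor probabilities, row-wise, with max-subtraction (equivalently
# min-subtraction on the distances) for overflow safety.
nca_probabilities <- function(dmat) {
  n <- nrow(dmat)
  m <- apply(dmat, 1L, min) # smallest distance per row; finite since n >= 2
  e <- exp(-sweep(dmat, 1L, m)) # exp(-(Inf - m)) = 0 handles the diagonal
  e / rowSums(e)
}

#' NCA feature-selection objective
#'
#' Evaluates the regularized expected leave-one-out 1-NN accuracy
#' `F(w) = mean_i p_i - lambda * sum_r w_r^2`, where `p_i` is sample i's
#' softmax probability mass on same-class neighbors under the weighted L1
#' distance `sum_r w_r^2 |x_ir - x_jr|`.
#'
#' @inheritParams split_features
#' @param weights Numeric vector of per-feature weights (length d, finite).
#' @param lambda Nonnegative L2 penalty.
#' @return A single number in `(-Inf, 1]`.
#' @examples
#' df <- tibble::tibble(f1 = c(0, 0, 1, 1), label = c("a", "a", "b", "b"))
#' nca_objective(df, weights = 0, lambda = 0) # uniform neighbors: 1/3
#' @export
nca_objective <- function(data, weights, lambda = 0, label_col = "label") {
  lm <- split_features(data, label_col, require_classes = 1L)
  check_weights(weights, ncol(lm$x))
  nca_objective_impl(lm$x, lm$y, weights, lambda)
}

nca_objective_impl <- function(x, y, weights, lambda) {
  p <- nca_probabilities(nca_distance_matrix(x, weights^2))
  same <- outer(y, y, "==")
  diag(same) <- FALSE
  mean(rowSums(p * same)) - lambda * sum(weights^2)
}

#' Analytic gradient of the NCA objective
#'
#' Closed-form `dF/dw_r` of [nca_objective()]:
#' `(1/n) sum_i 2 w_r (p_i sum_k p_ik |x_ir - x_kr| -
#'  sum_{j same class} p_ij |x_ir - x_jr|) - 2 lambda w_r`.
#'
#' @inheritParams nca_objective
#' @return Numeric vector of length d.
#' @export
nca_gradient <- function(data, weights, lambda = 0, label_col = "label") {
  lm <- split_features(data, label_col, require_classes = 1L)
  check_weights(weights, ncol(lm$x))
  x <- lm$x
  p <- nca_probabilities(nca_distance_matrix(x, weights^2))
  same <- outer(lm$y, lm$y, "==")
  diag(same) <- FALSE
  p_i <- rowSums(p * same)
  grad <- vapply(seq_len(ncol(x)), function(r) {
    a <- abs(outer(x[, r], x[, r], "-"))
    2 * weights[r] * mean(p_i * rowSums(p * a) - rowSums(p * same * a))
  }, numeric(1))
  grad - 2 * lambda * weights
}

#' Fit per-feature NCA weights by stochastic gradient ascent
#'
#' Learns a nonnegative weight per feature by per-sample stochastic gradient
#' ascent on the NCA feature-selection objective. All randomness (the per-epoch
#' sample visit order) is derived from `config$seed`, so identical inputs give
#' bit-identical weights.
#'
#' @inheritParams split_features
#' @param config An [nca_config()].
#' @return An object of class `nca_fit`: `weights` (named, nonnegative),
#'   `objective_trace` (epoch-end objective values), `converged` (whether the
#'   early-stopping rule fired), `lambda`, and the `config` used.
#' @examples
#' df <- make_planted_features(n = 60, informative = 2, noise = 4, seed = 1)
#' fit <- nca_fit(df, config = nca_config(seed = 1))
#' tidy(fit)
#' @export
nca_fit <- function(data, config = nca_config(), label_col = "label") {
  lm <- split_features(data, label_col)
  x <- lm$x
  y <- lm$y
  n <- nrow(x)
  d <- ncol(x)
  lambda <- config$lambda %||% (1 / n)
  same <- outer(y, y, "==")
  diag(same) <- FALSE

  w <- rep(1, d)
  trace <- numeric(0)
  converged <- FALSE
  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      lr <- config$learning_rate / sqrt(epoch)
      for (i in sample.int(n)) {
        diffs <- abs(x - matrix(x[i, ], n, d, byrow = TRUE))
        dist <- as.vector(diffs %*% (w * w))
        dist[i] <- Inf
        e <- exp(-(dist - min(dist)))
        e[i] <- 0
        p <- e / sum(e)
        msk <- same[, i]
        p_i <- sum(p[msk])
        grad <- 2 * w * (p_i * colSums(p * diffs) -
                           colSums(p[msk] * diffs[msk, , drop = FALSE])) -
          2 * lambda * w
        w <- w + lr * grad
      }
      trace <- c(trace, nca_objective_impl(x, y, w, lambda))
      if (length(trace) >= 4L) {
        last <- tail(trace, 4L)
        rel <- abs(diff(last)) / pmax(abs(last[-4L]), 1e-12)
        if (all(rel < config$tolerance)) {
          converged <- TRUE
          break
        }
      }
    }
  })

  structure(
    list(weights = setNames(abs(w), lm$feature_names),
         objective_trace = trace, converged = converged,
         lambda = lambda, config = config),
    class = "nca_fit"
  )
}

#' @export
print.nca_fit <- function(x, ...) {
  cat(sprintf("<nca_fit> %d features, %d epochs, objective %.6f%s\n",
              length(x$weights), length(x$objective_trace),
              tail(x$objective_trace, 1L),
              if (x$converged) " (converged)" else ""))
  top <- sort(x$weights, decreasing = TRUE)
  cat("top weights:", paste(sprintf("%s=%.3f", names(head(top, 5L)),
                                    head(top, 5L)), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname nca_fit
#' @param x An `nca_fit` object.
#' @param ... Unused.
#' @export
tidy.nca_fit <- function(x, ...) {
  tibble(feature = names(x$weights), weight = unname(x$weights)) |>
    dplyr::arrange(dplyr::desc(.data$weight)) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' @rdname nca_fit
#' @export
glance.nca_fit <- function(x, ...) {
  tibble(n_features = length(x$weights),
         epochs_run = length(x$objective_trace),
         final_objective = tail(x$objective_trace, 1L),
         lambda = x$lambda,
         converged = x$converged)
}

#' @rdname nca_fit
#' @param object An `nca_fit` object.
#' @export
autoplot.nca_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = stats::reorder(.data$feature, .data$weight),
                                   y = .data$weight)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "NCA feature weight")
}

#' Serialize / restore an NCA model as JSON
#'
#' @param fit An `nca_fit`.
#' @param path Output (input) file path.
#' @return `path` invisibly; `read_nca_json()` returns an `nca_fit`.
#' @export
write_nca_json <- function(fit, path) {
  stopifnot(inherits(fit, "nca_fit"))
  obj <- list(
    weights = as.list(fit$weights),
    objective_trace = fit$objective_trace,
    converged = fit$converged,
    config = list(lambda = fit$lambda,
                  learning_rate = fit$config$learning_rate,
                  epochs = fit$config$epochs,
                  tolerance = fit$config$tolerance,
                  seed = fit$config$seed)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_nca_json
#' @export
read_nca_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- nca_config(lambda = obj$config$lambda,
                    learning_rate = obj$config$learning_rate,
                    epochs = obj$config$epochs,
                    tolerance = obj$config$tolerance,
                    seed = obj$config$seed)
  structure(
    list(weights = unlist(obj$weights), objective_trace = obj$objective_trace,
         converged = obj$converged, lambda = obj$config$lambda, config = cfg),
    class = "nca_fit"
  )
}
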