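# Synthetic-data generators emulating the statistical structure the method
# assumes: feature matrices with planted informative dimensions,
# prediction-vector ensembles with controlled accuracies, and toy corpora
# with class-specific token pools. All are pure functions of their
# parameters and seed.

#' Generate a feature matrix with planted informative features
#'
#' Informative columns are class-conditional Gaussians with unit standard
#' deviation and class means spaced `class_sep` apart (for two classes,
#' means at +/- `class_sep`/2); noise columns are standard Gaussian,
#' independent of the labels. Classes are balanced to within one sample.
#' Informative columns come first and are named `"inf1" ...`; noise columns
#' `"noise1" ...`.
#'
#' @param n Number of samples.
#' @param classes Number of classes (>= 2).
#' @param informative Number of informative feature columns.
#' @param noise Number of label-independent noise columns.
#' @param class_sep Between-class mean separation, in units of the
#'   within-class standard deviation.
#' @param seed Integer seed; same seed, same matrix.
#' @return A tibble with `informative + noise` numeric columns and a `label`
#'   column (`"c1" ... "c<classes>"`).
#' @examples
#' make_planted_features(n = 20, informative = 2, noise = 3, seed = 1)
#' @export
make_planted_features <- function(n, classes = 2L, informative = 3L,
                                  noise = 17L, class_sep = 2, seed = 1L) {
  if (n < classes) abort("`n` must be at least `classes`.")
  if (classes < 2L) abort("`classes` must be >= 2.")
  if (informative < 1L || noise < 0L) abort("feature counts must be positive.")
  if (class_sep < 0) abort("`class_sep` must be nonnegative.")
  y <- rep_len(paste0("c", seq_len(classes)), n)
  centers <- (seq_len(classes) - (classes + 1) / 2) * class_sep
  withr::with_seed(seed, {
    xi <- matrix(stats::rnorm(n * informative), n, informative) +
      matrix(centers[match(y, paste0("c", seq_len(classes)))], n, informative)
    xn <- if (noise > 0L) matrix(stats::rnorm(n * noise), n, noise) else NULL
  })
  x <- cbind(xi, xn)
  colnames(x) <- c(paste0("inf", seq_len(informative)),
                   if (noise > 0L) paste0("noise", seq_len(noise)))
  out <- as_tibble(as.data.frame(x))
  out$label <- y
  out
}

#' Generate an ensemble of prediction vectors with controlled accuracies
#'
#' Truth is drawn uniformly over the classes; model i predicts the truth with
#' probability `model_accuracies[i]` and otherwise a uniformly chosen wrong
#' label. Errors are independent across models, isolating the
#' Condorcet-style mechanism by which majority voting over diverse models
#' beats each individual one.
#'
#' @param n Number of samples.
#' @param model_accuracies Vector of target per-model accuracies in `[0, 1]`.
#' @param classes Number of classes (>= 2); labels `"c1" ...`.
#' @param seed Integer seed.
#' @return A [prediction_set()] with realized (not target) accuracies.
#' @export
make_prediction_ensemble <- function(n, model_accuracies, classes = 2L, seed = 1L) {
  if (classes < 2L) abort("`classes` must be >= 2.")
  if (any(model_accuracies < 0 | model_accuracies > 1)) {
    abort("`model_accuracies` must lie in [0, 1].")
  }
  m <- length(model_accuracies)
  lvls <- paste0("c", seq_len(classes))
  withr::with_seed(seed, {
    truth <- sample(lvls, n, replace = TRUE)
    preds <- vapply(seq_len(m), function(i) {
      correct <- stats::runif(n) < model_accuracies[i]
      wrong <- vapply(truth, function(tl) sample(setdiff(lvls, tl), 1L), character(1))
      ifelse(correct, truth, wrong)
    }, character(n))
  })
  preds <- matrix(preds, nrow = n)
  df <- as_tibble(as.data.frame(preds))
  names(df) <- paste0("model", seq_len(m))
  prediction_set(df, truth = truth)
}

#' Generate a toy labeled text corpus with class-specific vocabularies
#'
#' Each class draws its tokens from a pool of `vocab_per_class` tokens, a
#' fraction `overlap` of which is shared across all classes (overlap 0 gives
#' disjoint vocabularies, overlap 1 identical pools). Each text is 5-20
#' tokens sampled with replacement from its class pool.
#'
#' @param n Number of texts.
#' @param classes Number of classes (>= 2).
#' @param vocab_per_class Tokens available to each class.
#' @param overlap Fraction of each class pool shared by all classes, in
#'   `[0, 1]`.
#' @param seed Integer seed.
#' @return A tibble with `text` and `label` columns.
#' @export
make_text_corpus <- function(n, classes = 2L, vocab_per_class = 50L,
                             overlap = 0, seed = 1L) {
  if (classes < 2L) abort("`classes` must be >= 2.")
  if (overlap < 0 || overlap > 1) abort("`overlap` must lie in [0, 1].")
  if (vocab_per_class < 1L) abort("`vocab_per_class` must be positive.")
  n_shared <- round(overlap * vocab_per_class)
  n_own <- vocab_per_class - n_shared
  shared <- if (n_shared > 0L) sprintf("shared%03d", seq_len(n_shared)) else character(0)
  pools <- lapply(seq_len(classes), function(k) {
    own <- if (n_own > 0L) sprintf("cls%d tok%03d", k, seq_len(n_own)) else character(0)
    c(gsub(" ", "", own), shared)
  })
  y <- rep_len(paste0("c", seq_len(classes)), n)
  withr::with_seed(seed, {
    lens <- sample(5:20, n, replace = TRUE)
    texts <- vapply(seq_len(n), function(i) {
      pool <- pools[[match(y[i], paste0("c", seq_len(classes)))]]
      paste(sample(pool, lens[i], replace = TRUE), collapse = " ")
    }, character(1))
  })
  tibble(text = texts, label = y)
}
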