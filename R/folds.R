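# Seeded cross-validation fold assignment, stratified by class where the
# class sizes permit it.

#' Assign stratified k-fold cross-validation folds
#'
#' Shuffles each class independently (from `seed`) and deals its members to
#' folds round-robin, so fold class proportions track the full data. If any
#' class has fewer members than `k`, stratification is impossible without
#' empty strata; the assignment degrades to plain seeded k-fold with a
#' warning.
#'
#' @param labels Vector of class labels, length n.
#' @param k Number of folds (`2 <= k <= n`).
#' @param seed Integer seed; fully determines the assignment.
#' @return Integer vector of fold ids in `1..k`, length n; every fold
#'   non-empty.
#' @export
stratified_folds <- function(labels, k = 10L, seed = 1L) {
  labels <- as.character(labels)
  n <- length(labels)
  k <- as.integer(k)
  if (k < 2L) abort("`k` must be at least 2.")
  if (k > n) abort(sprintf("`k` (%d) cannot exceed the number of samples (%d).", k, n))
  fold <- integer(n)
  withr::with_seed(seed, {
    sizes <- table(labels)
    if (any(sizes < k)) {
      warn(sprintf(
        "class(es) %s have fewer than %d members; falling back to non-stratified folds.",
        paste(names(sizes)[sizes < k], collapse = ", "), k
      ))
      ord <- sample.int(n)
      fold[ord] <- rep_len(seq_len(k), n)
    } else {
      for (cl in names(sizes)) {
        idx <- which(labels == cl)
        idx <- idx[sample.int(length(idx))]
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
    }
  })
  fold
}
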