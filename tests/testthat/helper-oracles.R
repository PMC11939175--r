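# Independent oracles: deliberately naive, loop-based re-implementations used
# only to check the package's vectorized code paths. They share nothing with
# the implementation beyond input formats.

# Brute-force NCA objective: enumerate every pairwise term, no vectorization.
bf_nca_objective <- function(x, y, w, lambda) {
  n <- nrow(x)
  total <- 0
  for (i in seq_len(n)) {
    num <- 0
    den <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      d <- 0
      for (r in seq_len(ncol(x))) d <- d + w[r]^2 * abs(x[i, r] - x[j, r])
      kern <- exp(-d)
      den <- den + kern
      if (y[j] == y[i]) num <- num + kern
    }
    if (den > 0) total <- total + num / den
  }
  unname(total / n - lambda * sum(w^2))
}

# Central finite differences of the package objective.
fd_nca_gradient <- function(data, w, lambda, step = 1e-5) {
  vapply(seq_along(w), function(r) {
    hi <- w; hi[r] <- hi[r] + step
    lo <- w; lo[r] <- lo[r] - step
    (nca_objective(data, hi, lambda) - nca_objective(data, lo, lambda)) / (2 * step)
  }, numeric(1))
}

# Fold-by-fold brute-force 1-NN CV loss: explicit loops, train-only
# standardization, cityblock distance, first-index tie-break.
bf_knn_cv_loss <- function(data, fold_ids, label_col = "label") {
  feats <- setdiff(names(data), label_col)
  x <- as.matrix(data[feats])
  y <- as.character(data[[label_col]])
  errors <- 0
  for (f in sort(unique(fold_ids))) {
    tr <- which(fold_ids != f)
    te <- which(fold_ids == f)
    mu <- numeric(ncol(x)); sg <- numeric(ncol(x))
    for (r in seq_len(ncol(x))) {
      mu[r] <- mean(x[tr, r])
      sg[r] <- stats::sd(x[tr, r])
      if (!is.finite(sg[r]) || sg[r] <= 0) sg[r] <- 1
    }
    for (i in te) {
      best_d <- Inf; best_j <- NA_integer_
      for (j in tr) {
        d <- 0
        for (r in seq_len(ncol(x))) {
          d <- d + abs((x[i, r] - mu[r]) / sg[r] - (x[j, r] - mu[r]) / sg[r])
        }
        if (d < best_d) { best_d <- d; best_j <- j }
      }
      if (y[best_j] != y[i]) errors <- errors + 1
    }
  }
  errors / nrow(x)
}

# Naive candidate-size sweep for CWINCA: evaluates every size with the
# brute-force CV loss and picks the first minimum.
bf_size_sweep <- function(norm_data, ranked, start_size, stop_size, fold_ids,
                          label_col = "label") {
  sizes <- start_size:stop_size
  losses <- numeric(length(sizes))
  for (si in seq_along(sizes)) {
    keep <- ranked[seq_len(sizes[si])]
    losses[si] <- bf_knn_cv_loss(norm_data[c(keep, label_col)], fold_ids, label_col)
  }
  best <- 1L
  for (si in seq_along(sizes)) if (losses[si] < losses[best]) best <- si
  list(losses = losses, chosen_size = sizes[best], best_loss = losses[best])
}

# Naive majority vote with the package's stated tie policy, written as loops.
bf_mode_vote <- function(pm) {
  n <- nrow(pm)
  out <- character(n)
  for (i in seq_len(n)) {
    votes <- as.character(pm[i, ])
    lvls <- sort(unique(votes))
    cnt <- vapply(lvls, function(l) sum(votes == l), numeric(1))
    tied <- lvls[cnt == max(cnt)]
    if (length(tied) == 1L) { out[i] <- tied; next }
    pick <- NA_character_
    for (v in votes) if (v %in% tied) { pick <- v; break }
    out[i] <- if (is.na(pick)) tied[1L] else pick
  }
  out
}

# A random labeled feature tibble for property tests.
rand_instance <- function(n, d, classes = 2L, seed = 1L) {
  withr::with_seed(seed, {
    x <- matrix(stats::rnorm(n * d), n, d)
    y <- sample(paste0("c", seq_len(classes)), n, replace = TRUE)
    while (length(unique(y)) < 2L) y <- sample(paste0("c", seq_len(classes)), n, replace = TRUE)
  })
  out <- tibble::as_tibble(as.data.frame(x))
  names(out) <- paste0("f", seq_len(d))
  out$label <- y
  out
}
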