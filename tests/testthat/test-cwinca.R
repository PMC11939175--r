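test_that("min-max normalization follows the range formula", {
  df <- tibble::tibble(a = c(1, 2, 3), b = c(7, 7, 7), c = c(-2, 0, 2),
                       label = c("x", "x", "y"))
  out <- minmax_normalize(df, epsilon = 1e-8)
  expect_equal(out$a, (c(1, 2, 3) - 1) / (2 + 1e-8))
  expect_equal(out$a[3], 0.999999995, tolerance = 1e-12)
  expect_equal(out$b, c(0, 0, 0)) # constant column: epsilon prevents 0/0
  # epsilon -> 0 limit recovers the plain affine map
  out2 <- minmax_normalize(df, epsilon = 1e-15)
  expect_equal(out2$c, c(0, 0.5, 1), tolerance = 1e-9)
  expect_identical(out$label, df$label)
  expect_true(all(as.matrix(out[1:3]) >= 0 & as.matrix(out[1:3]) < 1))
})

test_that("normalization rejects non-finite input", {
  df <- tibble::tibble(a = c(1, Inf, 3), label = c("x", "x", "y"))
  expect_error(minmax_normalize(df), "non-finite")
})

test_that("cumulative bounds reproduce hand-computed sweep limits", {
  b <- cumulative_bounds(c(0.4, 0.3, 0.2, 0.1))
  expect_equal(b$cumulative_weights, c(0.4, 0.7, 0.9, 1.0))
  expect_equal(b$start_size, 2L) # first cumulative weight >= 0.5
  expect_equal(b$stop_size, 4L)  # first >= 0.999

  # all-zero weights: no rank reaches either threshold
  b25 <- cumulative_bounds(rep(0, 25))
  expect_equal(b25$start_size, 10L) # fallback start
  expect_equal(b25$stop_size, 25L)  # fallback stop = d
  b6 <- cumulative_bounds(rep(0, 6))
  expect_equal(b6$start_size, 6L)   # fallback clamped to d
  expect_equal(b6$stop_size, 6L)

  expect_error(cumulative_bounds(c(0.2, -0.1)), "nonnegative")
})

test_that("weight ties rank by ascending original position", {
  b <- cumulative_bounds(c(a = 0.2, b = 0.5, c = 0.2, d = 0.1))
  expect_identical(b$ranked_features, c("b", "a", "c", "d"))
})

test_that("knn CV loss is zero on well-separated clusters", {
  df <- withr::with_seed(1, tibble::tibble(
    f1 = c(stats::rnorm(10, 0, 0.5), stats::rnorm(10, 100, 0.5)),
    f2 = c(stats::rnorm(10, 0, 0.5), stats::rnorm(10, 100, 0.5)),
    label = rep(c("A", "B"), each = 10)
  ))
  expect_equal(knn_cv_loss(df, cv_folds = 10, seed = 1), 0)
})

test_that("knn CV loss equals the brute-force fold-by-fold oracle", {
  # duplicated points with conflicting labels
  dup <- tibble::tibble(f1 = rep(1.5, 20), f2 = rep(-3, 20),
                        label = rep(c("A", "B"), times = 10))
  folds <- stratified_folds(dup$label, 10, seed = 4)
  expect_equal(knn_cv_loss(dup, fold_ids = folds),
               bf_knn_cv_loss(dup, folds))

  for (s in 1:5) {
    inst <- rand_instance(n = 40, d = 3, seed = s)
    folds <- stratified_folds(inst$label, 10, seed = s)
    expect_identical(knn_cv_loss(inst, fold_ids = folds),
                     bf_knn_cv_loss(inst, folds))
  }
})

test_that("fold assignment is stratified, seeded, and degrades with a warning", {
  y <- rep(c("A", "B"), times = c(40, 20))
  f1 <- stratified_folds(y, 10, seed = 3)
  f2 <- stratified_folds(y, 10, seed = 3)
  expect_identical(f1, f2)
  expect_setequal(unique(f1), 1:10)
  for (k in 1:10) { # each fold preserves the 2:1 class ratio
    expect_equal(sum(y[f1 == k] == "A"), 4)
    expect_equal(sum(y[f1 == k] == "B"), 2)
  }
  y_small <- c(rep("A", 15), rep("B", 3))
  expect_warning(stratified_folds(y_small, 10, seed = 1), "fewer than 10")
  expect_error(stratified_folds(y, 100, seed = 1), "cannot exceed")
})

test_that("cwinca selection matches a naive enumeration of candidate sizes", {
  df <- make_planted_features(n = 50, informative = 2, noise = 2,
                              class_sep = 1.5, seed = 9)
  tr <- cwinca_select(df, config = cwinca_config(cv_folds = 5, seed = 9),
                      nca = nca_config(seed = 9))
  folds <- stratified_folds(df$label, 5, seed = 9)
  norm <- minmax_normalize(df, epsilon = tr$config$epsilon)
  oracle <- bf_size_sweep(norm, tr$ranked_features, tr$start_size,
                          tr$stop_size, folds)
  expect_equal(tr$losses, oracle$losses)
  expect_equal(tr$chosen_size, oracle$chosen_size)
  expect_identical(tr$best_loss, oracle$best_loss)
})

test_that("selection trace satisfies its self-consistency invariants", {
  for (s in 1:6) {
    dims <- withr::with_seed(400 + s, c(sample(20:40, 1), sample(3:8, 1)))
    inst <- rand_instance(n = dims[1], d = dims[2], seed = s)
    tr <- cwinca_select(inst, config = cwinca_config(cv_folds = 4, seed = s),
                        nca = nca_config(seed = s, epochs = 15))
    expect_true(!is.unsorted(tr$cumulative_weights))
    expect_equal(tail(tr$cumulative_weights, 1), 1)
    expect_lte(tr$start_size, tr$stop_size)
    expect_lte(tr$stop_size, dims[2])
    expect_gte(tr$chosen_size, tr$start_size)
    expect_lte(tr$chosen_size, tr$stop_size)
    expect_length(tr$losses, tr$stop_size - tr$start_size + 1)
    expect_equal(tr$best_loss, min(tr$losses))
    expect_equal(tr$losses[tr$chosen_size - tr$start_size + 1], tr$best_loss)
    expect_identical(tr$selected_features,
                     tr$ranked_features[seq_len(tr$chosen_size)])
    # nested subsets: size-s selection is a prefix of size-(s+1)
    expect_identical(names(tr$selected_data),
                     c(tr$selected_features, "label"))
  }
})

test_that("a single feature selects itself", {
  df <- make_planted_features(n = 30, informative = 1, noise = 0,
                              class_sep = 2, seed = 2)
  tr <- cwinca_select(df, config = cwinca_config(cv_folds = 5, seed = 2),
                      nca = nca_config(seed = 2, epochs = 10))
  expect_equal(tr$start_size, 1L)
  expect_equal(tr$stop_size, 1L)
  expect_equal(tr$chosen_size, 1L)
  expect_identical(tr$selected_features, "inf1")
})

test_that("selection is deterministic and its trace serializes", {
  df <- make_planted_features(n = 40, informative = 2, noise = 4, seed = 6)
  cfg <- cwinca_config(cv_folds = 5, seed = 6)
  nc <- nca_config(seed = 6, epochs = 15)
  t1 <- cwinca_select(df, config = cfg, nca = nc)
  t2 <- cwinca_select(df, config = cfg, nca = nc)
  expect_identical(t1$losses, t2$losses)
  expect_identical(t1$selected_features, t2$selected_features)

  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_trace_json(t1, p1)
  write_trace_json(t2, p2)
  expect_identical(readLines(p1), readLines(p2)) # bit-exact serialization

  td <- tidy(t1)
  expect_equal(nrow(td), t1$stop_size - t1$start_size + 1)
  expect_equal(sum(td$chosen), 1)
  expect_s3_class(autoplot(t1), "ggplot")
  expect_equal(glance(t1)$chosen_size, t1$chosen_size)
})

test_that("selected features beat the full set on planted fixtures", {
  wins <- 0L
  recovered <- 0L
  for (s in 1:3) { # desk-size spot check; the full 10-seed sweep runs in the acceptance suite
    df <- make_planted_features(n = 120, informative = 3, noise = 17,
                                class_sep = 2, seed = s)
    tr <- cwinca_select(df, config = cwinca_config(seed = s),
                        nca = nca_config(seed = s))
    if (all(paste0("inf", 1:3) %in% tr$selected_features)) recovered <- recovered + 1L
    full_loss <- knn_cv_loss(minmax_normalize(df),
                             fold_ids = stratified_folds(df$label, 10, seed = s))
    if (tr$best_loss <= full_loss) wins <- wins + 1L
  }
  expect_gte(recovered, 2L)
  expect_gte(wins, 2L)
})
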