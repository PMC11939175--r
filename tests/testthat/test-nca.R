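test_that("objective matches closed-form values in degenerate cases", {
  # zero weights force uniform neighbor probabilities: p_i = 1/3 for 4 samples
  df <- tibble::tibble(f1 = c(0.3, -1, 2, 5), label = c("A", "A", "B", "B"))
  expect_equal(nca_objective(df, weights = 0, lambda = 0), 1 / 3)

  # two samples, different classes: no same-class neighbor exists, F = 0
  df2 <- tibble::tibble(f1 = c(0, 1), f2 = c(2, -1), label = c("A", "B"))
  for (w in list(c(0, 0), c(1, 2), c(-0.5, 3))) {
    expect_equal(nca_objective(df2, weights = w, lambda = 0), 0)
  }
})

test_that("objective equals the brute-force pairwise enumeration oracle", {
  # fixed 6 x 2 fixture
  x <- matrix(c(0.1, 1.2, -0.7, 2.0, 0.0, -1.5,
                1.0, 0.3, 0.8, -0.2, 1.7, 0.5), ncol = 2)
  y <- c("A", "A", "A", "B", "B", "B")
  df <- tibble::tibble(f1 = x[, 1], f2 = x[, 2], label = y)
  expect_equal(nca_objective(df, weights = c(1, 1), lambda = 0.1),
               bf_nca_objective(x, y, c(1, 1), 0.1))

  for (s in 1:5) {
    inst <- rand_instance(n = 8, d = 3, seed = s)
    w <- withr::with_seed(100 + s, stats::runif(3, 0, 2))
    expect_equal(
      nca_objective(inst, weights = w, lambda = 0.05),
      bf_nca_objective(as.matrix(inst[1:3]), inst$label, w, 0.05)
    )
  }
})

test_that("objective is invariant under permutation of samples", {
  inst <- rand_instance(n = 15, d = 4, seed = 7)
  w <- c(0.5, 1.5, 0.2, 0.9)
  base <- nca_objective(inst, weights = w, lambda = 0.1)
  for (s in 1:5) {
    perm <- withr::with_seed(s, sample.int(nrow(inst)))
    expect_equal(nca_objective(inst[perm, ], weights = w, lambda = 0.1), base,
                 tolerance = 1e-12)
  }
})

test_that("rescaling a feature by c and its weight by 1/sqrt(c) preserves the data term", {
  # w_r^2 |x_ir - x_jr| is invariant under (x_r, w_r) -> (c x_r, w_r / sqrt(c))
  for (s in 1:5) {
    inst <- rand_instance(n = 10, d = 3, seed = s)
    w <- withr::with_seed(200 + s, stats::runif(3, 0.2, 2))
    cc <- withr::with_seed(300 + s, stats::runif(1, 0.5, 4))
    scaled <- inst
    scaled$f2 <- scaled$f2 * cc
    w_scaled <- w
    w_scaled[2] <- w[2] / sqrt(cc)
    expect_equal(nca_objective(scaled, weights = w_scaled, lambda = 0),
                 nca_objective(inst, weights = w, lambda = 0))
  }
})

test_that("objective and gradient reject malformed weights", {
  inst <- rand_instance(n = 6, d = 3, seed = 1)
  expect_error(nca_objective(inst, weights = c(1, 1), lambda = 0), "length 2.*3 features")
  expect_error(nca_gradient(inst, weights = c(1, NA, 1), lambda = 0), "finite")
})

test_that("gradient is exact in analytically known cases", {
  # two samples, different classes: F identically 0 around w = 0
  df2 <- tibble::tibble(f1 = c(0, 1), label = c("A", "B"))
  expect_equal(nca_gradient(df2, weights = 0, lambda = 0), 0)

  # identical rows: data term vanishes, gradient = -2 lambda w exactly
  df3 <- tibble::tibble(f1 = rep(1, 4), f2 = rep(-2, 4),
                        label = c("A", "A", "B", "B"))
  w <- c(0.7, 1.3)
  expect_equal(nca_gradient(df3, weights = w, lambda = 0.25), -2 * 0.25 * w)
})

test_that("gradient agrees with central finite differences", {
  for (s in 1:20) {
    dims <- withr::with_seed(1000 + s, c(sample(4:12, 1), sample(2:5, 1)))
    inst <- rand_instance(n = dims[1], d = dims[2], seed = s)
    w <- withr::with_seed(2000 + s, stats::runif(dims[2], 0.1, 1.5))
    lambda <- 0.1
    ana <- nca_gradient(inst, weights = w, lambda = lambda)
    num <- fd_nca_gradient(inst, w, lambda)
    expect_lt(max(abs(ana - num) / pmax(abs(num), 1e-8)), 1e-4)
  }
})

test_that("fitting is deterministic given the seed and errors on bad labels", {
  df <- make_planted_features(n = 40, informative = 2, noise = 3, seed = 3)
  f1 <- nca_fit(df, nca_config(seed = 11))
  f2 <- nca_fit(df, nca_config(seed = 11))
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$objective_trace, f2$objective_trace)
  f3 <- nca_fit(df, nca_config(seed = 12))
  expect_false(identical(f1$weights, f3$weights))

  single <- df
  single$label <- "A"
  expect_error(nca_fit(single), ">= 2 classes")
  expect_error(nca_fit(df[1, ]), "at least 2 samples")
})

test_that("fitted weights are nonnegative and the smoothed trace improves", {
  df <- make_planted_features(n = 80, informative = 2, noise = 6,
                              class_sep = 2, seed = 5)
  fit <- nca_fit(df, nca_config(seed = 5))
  expect_true(all(fit$weights >= 0))
  expect_true(all(is.finite(fit$weights)))
  expect_gt(length(fit$objective_trace), 0)
  # epoch-end objective ends above where it started (noisy but improving)
  expect_gt(tail(fit$objective_trace, 1), fit$objective_trace[1] - 1e-8)
})

test_that("a perfectly separating feature earns the top weight", {
  ok <- 0L
  for (s in 1:10) {
    df <- withr::with_seed(s, {
      y <- rep(c("A", "B"), each = 25)
      tibble::tibble(
        sep = ifelse(y == "A", 0, 4) + stats::rnorm(50, sd = 0.3),
        !!!setNames(as.list(as.data.frame(matrix(stats::rnorm(50 * 9), 50, 9))),
                    paste0("noise", 1:9)),
        label = y
      )
    })
    fit <- nca_fit(df, nca_config(seed = s))
    if (names(which.max(fit$weights)) == "sep") ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})

test_that("label permutation with lambda = 1/n shrinks the weights", {
  # the solver operates on min-max-normalized features (the selection
  # algorithm normalizes before fitting); on that scale the softmax stays
  # soft and the regularizer can pull uninformative weights down
  ok <- 0L
  for (s in 1:10) {
    df <- minmax_normalize(make_planted_features(n = 100, informative = 3,
                                                 noise = 7, class_sep = 2,
                                                 seed = s))
    fit_true <- nca_fit(df, nca_config(seed = s))
    null_df <- df
    null_df$label <- withr::with_seed(9000 + s, sample(df$label))
    fit_null <- nca_fit(null_df, nca_config(seed = s))
    if (max(fit_null$weights) < 0.5 * max(fit_true$weights)) ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})

test_that("nca model JSON serialization round-trips", {
  df <- make_planted_features(n = 30, informative = 2, noise = 2, seed = 2)
  fit <- nca_fit(df, nca_config(seed = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_nca_json(fit, path)
  back <- read_nca_json(path)
  expect_equal(back$weights, fit$weights)
  expect_equal(back$objective_trace, fit$objective_trace)
  expect_identical(back$converged, fit$converged)
})

test_that("tidy/glance expose weights and fit diagnostics", {
  df <- make_planted_features(n = 30, informative = 2, noise = 2, seed = 2)
  fit <- nca_fit(df, nca_config(seed = 2))
  td <- tidy(fit)
  expect_named(td, c("feature", "weight", "rank"))
  expect_equal(nrow(td), 4)
  expect_true(!is.unsorted(rev(td$weight)))
  gl <- glance(fit)
  expect_equal(gl$n_features, 4)
  expect_s3_class(autoplot(fit), "ggplot")
})
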