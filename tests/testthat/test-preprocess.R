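make_train <- function(seed = 4, n = 80, miss = 0) {
  co <- median_split_label(generate_cohort(synthetic_config(
    n_participants = n, group_shift = 0.3, legacy_strength = 0.2, seed = seed)))
  if (miss > 0) co <- inject_missingness(co, miss, seed = seed + 1)
  co
}

test_that("imputation uses training-feature medians", {
  tab <- as_cohort(data.frame(
    id = 1:4, group = c("man", "woman", "man", "woman"),
    feat_1 = c(1, NA, 3, 2), feat_2 = c(5, 6, 7, 8),
    score = 1:4, label = c(0L, 1L, 1L, 0L)), privileged = "man")
  fit <- fit_preprocess(tab, preprocess_config(n_components = 2))
  expect_equal(unname(fit$medians), c(2, 6.5))
})

test_that("standardization parameters come from the imputed training matrix", {
  train <- make_train(miss = 0.1)
  fit <- fit_preprocess(train, preprocess_config())
  X <- cohort_features(train)
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    x[is.na(x)] <- stats::median(x, na.rm = TRUE)
    expect_equal(unname(fit$means[j]), mean(x), tolerance = 1e-12)
    expect_equal(unname(fit$sds[j]), stats::sd(x), tolerance = 1e-12)
    # z-scored column has mean 0, unit variance
    z <- (x - mean(x)) / stats::sd(x)
    expect_lt(abs(mean(z)), 1e-9)
    expect_lt(abs(stats::var(z) - 1), 1e-9)
  }
})

test_that("retained components are orthonormal with nonincreasing variance ratios", {
  fit <- fit_preprocess(make_train(), preprocess_config())
  gram <- crossprod(fit$rotation)
  expect_lt(max(abs(gram - diag(ncol(fit$rotation)))), 1e-8)
  expect_true(all(diff(fit$explained_variance) <= 1e-12))
  expect_lte(sum(fit$explained_variance), 1 + 1e-12)
})

test_that("five components carry >99% of variance for generated cohorts", {
  # eigendecomposition oracle on the standardized train covariance
  train <- median_split_label(generate_cohort(synthetic_config(seed = 21)))
  fit <- fit_preprocess(train, preprocess_config())
  expect_equal(fit$n_components, 5)
  X <- scale(cohort_features(train))
  ev <- eigen(stats::cov(X), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(sum(ev[1:5]) / sum(ev), 0.99)
  expect_gt(sum(fit$explained_variance[1:5]), 0.99)
})

test_that("applying the fitted chain reproduces the training projection", {
  train <- make_train()
  fit <- fit_preprocess(train, preprocess_config())
  reapplied <- apply_preprocess(fit, train)
  expect_equal(unname(fit$train_X[seq_len(nrow(train)), ]), unname(reapplied),
               tolerance = 1e-10)
  # a row sitting at the fitted means projects exactly to the origin
  mu <- as.data.frame(as.list(stats::setNames(fit$means, names(fit$medians))))
  expect_equal(unname(drop(apply_preprocess(fit, as.matrix(mu)))),
               rep(0, fit$n_components), tolerance = 1e-12)
})

test_that("empty tables and dimension mismatches are handled", {
  fit <- fit_preprocess(make_train(), preprocess_config())
  out <- apply_preprocess(fit, matrix(numeric(0), nrow = 0, ncol = 10))
  expect_equal(dim(out), c(0, 5))
  expect_error(apply_preprocess(fit, matrix(0, 2, 3)),
               class = "fairaudit_config_error")
})

test_that("held-out rows cannot influence the fitted transform", {
  cohort <- make_train(n = 100)
  train <- cohort[1:70, ]
  test <- cohort[71:100, ]
  fit1 <- fit_preprocess(train, preprocess_config(seed = 9))
  test$feat_1 <- test$feat_1 * 1000 + 5
  fit2 <- fit_preprocess(train, preprocess_config(seed = 9))
  expect_identical(fit1, fit2)
})

test_that("degenerate features are reported", {
  tab <- as_cohort(data.frame(
    id = 1:4, group = c("man", "woman", "man", "woman"),
    feat_1 = NA_real_, feat_2 = c(1, 2, 3, 4),
    score = 1:4, label = c(0L, 1L, 0L, 1L)), privileged = "man")
  expect_error(fit_preprocess(tab, preprocess_config(n_components = 1)),
               "feat_1", class = "fairaudit_config_error")
  tab$feat_1 <- 7
  expect_warning(fit_preprocess(tab, preprocess_config(n_components = 1)),
                 "zero-variance")
})

test_that("SMOTE leaves balanced input untouched and balances the rest", {
  withr::with_seed(31, {
    X <- matrix(rnorm(80), 40, 2)
    y <- rep(c(0L, 1L), 20)
  })
  out <- smote_oversample(X, y, k = 5, seed = 1)
  expect_identical(out$X, X)
  expect_identical(out$y, y)

  withr::with_seed(32, {
    X <- rbind(matrix(rnorm(60, mean = 0), 30, 2), matrix(rnorm(20, mean = 4), 10, 2))
    y <- c(rep(0L, 30), rep(1L, 10))
  })
  out <- smote_oversample(X, y, k = 3, seed = 7)
  expect_equal(sum(out$y == 0), sum(out$y == 1))
  expect_equal(nrow(out$X), 60)
  # originals preserved unchanged, in place
  expect_identical(out$X[1:40, ], X)
  expect_identical(smote_oversample(X, y, k = 3, seed = 7)$X, out$X)
})

test_that("synthetic SMOTE points lie on minority nearest-neighbor segments", {
  # collinear two-point minority: every synthetic point is (u, u)
  X <- rbind(matrix(5 + abs(rnorm(20)), 10, 2), c(0, 0), c(1, 1))
  y <- c(rep(0L, 10), 1L, 1L)
  out <- smote_oversample(X, y, k = 1, seed = 3)
  synth <- out$X[13:20, , drop = FALSE]
  expect_equal(synth[, 1], synth[, 2], tolerance = 1e-12)
  expect_true(all(synth >= -1e-12 & synth <= 1 + 1e-12))

  withr::with_seed(33, {
    Xb <- rbind(matrix(rnorm(60), 30, 2), matrix(rnorm(20, mean = 3), 10, 2))
    yb <- c(rep(0L, 30), rep(1L, 10))
  })
  outb <- smote_oversample(Xb, yb, k = 4, seed = 11)
  minority <- Xb[yb == 1L, ]
  for (r in 41:nrow(outb$X)) {
    expect_true(on_neighbor_segment(outb$X[r, ], minority, k = 4))
  }
})

test_that("SMOTE rejects unusable class structure", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(smote_oversample(X, rep(0L, 10), k = 5, seed = 1),
               class = "fairaudit_config_error")
  expect_error(smote_oversample(X, c(rep(0L, 9), 1L), k = 5, seed = 1),
               class = "fairaudit_config_error")
})
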