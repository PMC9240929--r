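#' Preprocessing configuration
#'
#' Parameters for the per-fold preprocessing chain: median imputation,
#' z-standardization, SMOTE oversampling of the training minority class, and
#' PCA projection. Defaults mirror common practice for small behavioral
#' cohorts: SMOTE with 5 neighbors and 5 retained principal components
#' (enough to carry >99% of variance when the feature block is effectively
#' rank 5).
#'
#' @param smote_k Neighbor count for SMOTE (default 5). When the minority
#'   class is smaller than `smote_k + 1`, `minority size - 1` neighbors are
#'   used instead.
#' @param n_components Number of principal components to retain (default 5);
#'   capped at the rank of the training matrix. When the rank is below
#'   `n_components`, enough components are kept to reach `variance_target`.
#' @param variance_target Cumulative explained-variance fallback in (0, 1\]
#'   (default 0.99).
#' @param smote_first If `TRUE` (default) PCA is fitted on the SMOTE-balanced
#'   standardized matrix; if `FALSE`, on the original standardized matrix.
#'   The narrative order of the emulated protocol lists SMOTE first; the
#'   alternative is exposed because the order is a genuine design choice.
#' @param seed Integer seed for SMOTE sampling.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(smote_k = 5, n_components = 5,
                              variance_target = 0.99, smote_first = TRUE,
                              seed = 1L) {
  check_count(smote_k, "smote_k", min = 1)
  check_count(n_components, "n_components", min = 1)
  if (!is.numeric(variance_target) || length(variance_target) != 1 ||
      is.na(variance_target) || variance_target <= 0 || variance_target > 1) {
    stop_config("variance_target must be a single number in (0, 1]")
  }
  check_count(seed, "seed", min = -.Machine$integer.max)
  structure(
    list(smote_k = as.integer(smote_k), n_components = as.integer(n_components),
         variance_target = variance_target, smote_first = isTRUE(smote_first),
         seed = as.integer(seed)),
    class = "preprocess_config"
  )
}

#' Fit the preprocessing chain on a training table
#'
#' Computes, on the training rows only: per-feature medians (for imputation),
#' per-feature means and SDs of the imputed matrix (for standardization),
#' then oversamples the training minority class with SMOTE and fits PCA on
#' the balanced standardized matrix. Nothing from held-out rows can reach
#' any fitted parameter.
#'
#' Zero-variance features are scaled by 1 (with a warning) rather than
#' dividing by zero.
#'
#' @param train A labeled cohort table (or a list with elements `X` feature
#'   matrix and `y` 0/1 labels).
#' @param config A [preprocess_config()].
#' @return An object of class `fitted_transform` with fields `medians`,
#'   `means`, `sds`, `rotation` (orthonormal loading matrix, one column per
#'   retained component), `explained_variance` (ratios over all components,
#'   nonincreasing), `train_X` (balanced projected training matrix) and
#'   `train_y` (balanced labels).
#' @export
fit_preprocess <- function(train, config = preprocess_config()) {
  if (inherits(train, "cohort")) {
    if (is.null(train$label)) stop_config("training cohort must be labeled")
    X <- cohort_features(train)
    y <- train$label
  } else {
    X <- as.matrix(train$X)
    y <- as.integer(train$y)
  }
  if (nrow(X) < 2) stop_config("training table must have at least 2 rows")
  if (ncol(X) < 1) stop_config("training table must have at least 1 feature")

  medians <- apply(X, 2, stats::median, na.rm = TRUE)
  all_missing <- vapply(seq_len(ncol(X)), function(j) all(is.na(X[, j])), logical(1))
  if (any(all_missing)) {
    stop_config(paste("feature(s) entirely missing:",
                      paste(colnames(X)[all_missing], collapse = ", ")))
  }
  Ximp <- impute_with(X, medians)
  means <- colMeans(Ximp)
  sds <- apply(Ximp, 2, stats::sd)
  zero_var <- sds == 0 | !is.finite(sds)
  if (any(zero_var)) {
    warning(sprintf("zero-variance feature(s) scaled by 1: %s",
                    paste(colnames(X)[zero_var], collapse = ", ")))
    sds[zero_var] <- 1
  }
  Z <- scale_with(Ximp, means, sds)

  if (config$smote_first) {
    bal <- smote_oversample(Z, y, k = config$smote_k, seed = config$seed)
    pca_input <- bal$X
  } else {
    bal <- list(X = Z, y = y)
    pca_input <- Z
  }
  pca <- stats::prcomp(pca_input, center = FALSE, scale. = FALSE)
  ev <- pca$sdev^2
  ratios <- ev / sum(ev)
  rank <- sum(pca$sdev > max(pca$sdev) * 1e-8)
  n_keep <- min(config$n_components, rank)
  if (rank < config$n_components) {
    # fallback: enough components for the variance target, still <= rank
    n_keep <- max(n_keep, min(rank, which(cumsum(ratios) >= config$variance_target)[1]))
  }
  rotation <- pca$rotation[, seq_len(n_keep), drop = FALSE]

  out_bal <- if (config$smote_first) bal else
    smote_oversample(Z, y, k = config$smote_k, seed = config$seed)

  structure(
    list(medians = medians, means = means, sds = sds,
         rotation = rotation, explained_variance = ratios,
         n_components = n_keep,
         train_X = out_bal$X %*% rotation, train_y = out_bal$y),
    class = "fitted_transform"
  )
}

#' Apply a fitted preprocessing chain to new rows
#'
#' Imputes, standardizes and projects `table` using only parameters fitted
#' on the training rows; never refits and never oversamples (held-out folds
#' keep their original class ratio).
#'
#' @param transform A `fitted_transform` from [fit_preprocess()].
#' @param table A cohort table or feature matrix with the fitted columns.
#' @return Numeric matrix in component space, one row per input row.
#' @export
apply_preprocess <- function(transform, table) {
  stopifnot(inherits(transform, "fitted_transform"))
  X <- if (inherits(table, "cohort") || is.data.frame(table)) {
    cohort_features(table)
  } else {
    as.matrix(table)
  }
  if (nrow(X) == 0) {
    return(matrix(numeric(0), nrow = 0, ncol = ncol(transform$rotation)))
  }
  if (ncol(X) != length(transform$medians)) {
    stop_config(sprintf("feature dimension mismatch: fitted %d, got %d",
                        length(transform$medians), ncol(X)))
  }
  Z <- scale_with(impute_with(X, transform$medians), transform$means, transform$sds)
  Z %*% transform$rotation
}

impute_with <- function(X, medians) {
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- medians[j]
  }
  X
}

scale_with <- function(X, means, sds) {
  sweep(sweep(X, 2, means, "-"), 2, sds, "/")
}

#' SMOTE: synthetic minority oversampling
#'
#' Balances a two-class sample by interpolating new minority points. Each
#' synthetic point is `x + u * (x' - x)` where `x` is a minority row drawn
#' uniformly, `x'` one of its `k` nearest minority neighbors (Euclidean),
#' and `u ~ Uniform(0, 1)`. Original rows are preserved unchanged; synthetic
#' rows are appended until both classes have equal counts.
#'
#' @param X Numeric feature matrix.
#' @param y 0/1 labels, one per row of `X`.
#' @param k Neighbor count; reduced to `minority size - 1` when the minority
#'   class is too small.
#' @param seed Integer seed; output is a pure function of `(X, y, k, seed)`.
#' @return List with the augmented matrix `X` and label vector `y`.
#' @export
smote_oversample <- function(X, y, k = 5, seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y))
  counts <- table(factor(y, levels = c(0L, 1L)))
  if (any(counts == 0)) stop_config("SMOTE requires both classes present")
  if (counts[["0"]] == counts[["1"]]) return(list(X = X, y = y))
  minority_class <- if (counts[["0"]] < counts[["1"]]) 0L else 1L
  minority_idx <- which(y == minority_class)
  n_min <- length(minority_idx)
  if (n_min < 2) stop_config("SMOTE requires a minority class of size >= 2")
  n_new <- abs(counts[["1"]] - counts[["0"]])
  k_eff <- min(k, n_min - 1)

  M <- X[minority_idx, , drop = FALSE]
  d2 <- as.matrix(stats::dist(M))^2
  diag(d2) <- Inf
  # k nearest minority neighbors of each minority point
  nn <- t(apply(d2, 1, function(row) order(row)[seq_len(k_eff)]))
  if (k_eff == 1) nn <- matrix(nn, ncol = 1)

  withr::with_seed(as.integer(seed), {
    base_i <- sample.int(n_min, n_new, replace = TRUE)
    nb_j <- sample.int(k_eff, n_new, replace = TRUE)
    u <- stats::runif(n_new)
  })
  base <- M[base_i, , drop = FALSE]
  neigh <- M[nn[cbind(base_i, nb_j)], , drop = FALSE]
  synthetic <- base + u * (neigh - base)
  list(X = rbind(X, synthetic), y = c(y, rep(minority_class, n_new)))
}
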