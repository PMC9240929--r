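#' Specify one of the five audited classifier families
#'
#' The audit evaluates logistic regression, a support-vector machine (RBF
#' kernel), a random forest (100 trees, depth capped at 6), k-nearest
#' neighbors, and a single-hidden-layer perceptron, all behind one
#' fit/predict contract. Hyperparameters beyond those listed default to the
#' backing library's defaults and can be overridden through `...`; the audit
#' studies group disparity, not tuning.
#'
#' @param family One of `"logistic_regression"`, `"svm"`, `"random_forest"`,
#'   `"knn"`, `"mlp"`.
#' @param ... Family-specific hyperparameter overrides: `num.trees`,
#'   `max.depth` (random forest); `k` (knn, default 5); `size`, `maxit`,
#'   `decay` (mlp); `kernel`, `cost`, `gamma` (svm).
#' @param seed Integer seed making training deterministic.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("logistic_regression", "svm",
                                       "random_forest", "knn", "mlp"),
                            ..., seed = 1L) {
  if (length(family) != 1 && !identical(family, eval(formals(classifier_spec)$family))) {
    family <- family[1]
  }
  family <- tryCatch(match.arg(family),
                     error = function(e) stop_config(
                       sprintf("unknown classifier family '%s'", family[1])))
  check_count(seed, "seed", min = -.Machine$integer.max)
  hyper <- list(...)
  defaults <- switch(family,
    random_forest = list(num.trees = 100, max.depth = 6),
    knn = list(k = 5),
    mlp = list(size = 8, maxit = 1000, decay = 1e-3),
    svm = list(kernel = "radial"),
    logistic_regression = list()
  )
  for (nm in names(defaults)) {
    if (is.null(hyper[[nm]])) hyper[[nm]] <- defaults[[nm]]
  }
  structure(list(family = family, hyperparameters = hyper, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Train a classifier
#'
#' @param spec A [classifier_spec()].
#' @param X Numeric feature matrix.
#' @param y 0/1 labels (both classes must be present).
#' @return A `fairaudit_model` usable with [predict_classifier()].
#' @export
train_classifier <- function(spec, X, y) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- as.matrix(X)
  y <- as.integer(y)
  if (nrow(X) != length(y)) stop_config("X rows must match y length")
  if (length(unique(y)) < 2) stop_config("training labels must contain both classes")
  h <- spec$hyperparameters
  df <- as.data.frame(X)
  names(df) <- paste0("V", seq_len(ncol(X)))
  fit <- withr::with_seed(spec$seed, switch(spec$family,
    logistic_regression = {
      df$.y <- y
      suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
    },
    svm = do.call(e1071::svm, c(list(x = X, y = factor(y, levels = c(0L, 1L))), h)),
    random_forest = {
      df$.y <- factor(y, levels = c(0L, 1L))
      do.call(ranger::ranger,
              c(list(dependent.variable.name = ".y", data = df,
                     seed = spec$seed, num.threads = 1), h))
    },
    knn = list(train_X = X, train_y = y, k = h$k),  # lazy learner
    mlp = {
      args <- c(list(x = X, y = y, entropy = TRUE, trace = FALSE), h)
      suppressWarnings(do.call(nnet::nnet, args))
    }
  ))
  structure(list(spec = spec, fit = fit, p = ncol(X)), class = "fairaudit_model")
}

#' Predict 0/1 labels
#'
#' @param model A `fairaudit_model` from [train_classifier()].
#' @param X Numeric feature matrix with the training dimensionality.
#' @return Integer vector of 0/1 labels, one per row (length 0 for empty `X`).
#' @export
predict_classifier <- function(model, X) {
  stopifnot(inherits(model, "fairaudit_model"))
  X <- as.matrix(X)
  if (nrow(X) == 0) return(integer(0))
  if (ncol(X) != model$p) {
    stop_config(sprintf("feature dimension mismatch: trained on %d, got %d",
                        model$p, ncol(X)))
  }
  df <- as.data.frame(X)
  names(df) <- paste0("V", seq_len(ncol(X)))
  spec <- model$spec
  out <- switch(spec$family,
    logistic_regression = as.integer(
      stats::predict(model$fit, newdata = df, type = "response") > 0.5),
    svm = as.integer(as.character(stats::predict(model$fit, X))),
    random_forest = as.integer(as.character(
      stats::predict(model$fit, data = df, num.threads = 1)$predictions)),
    knn = {
      # vote ties are broken by the RNG; pin it so prediction is a pure
      # function of (spec, training data, X)
      pred <- withr::with_seed(spec$seed,
        class::knn(train = model$fit$train_X, test = X,
                   cl = factor(model$fit$train_y, levels = c(0L, 1L)),
                   k = model$fit$k, use.all = TRUE))
      as.integer(as.character(pred))
    },
    mlp = as.integer(stats::predict(model$fit, X) > 0.5)
  )
  as.integer(out)
}

#' Majority-class baseline
#'
#' Predicts the most frequent training label for every row; ties go to 0.
#' Used as the floor every real family must beat on separable data.
#'
#' @param y Training labels.
#' @return A function of a matrix `X` returning constant labels.
#' @export
majority_baseline <- function(y) {
  y <- as.integer(y)
  lab <- if (sum(y == 1L) > sum(y == 0L)) 1L else 0L
  function(X) rep(lab, nrow(as.matrix(X)))
}
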