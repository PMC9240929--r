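#' Configuration for the repeated cross-validated audit
#'
#' One audit = `n_iterations` shuffled repetitions of stratified
#' `n_folds`-fold cross-validation of one classifier on one labeled cohort,
#' each iteration pooling its out-of-fold predictions into a fairness
#' report. Setting `repair_lambda` inserts a disparate impact remover,
#' fitted on each training fold only, ahead of the preprocessing chain.
#'
#' @param n_folds Folds per iteration (default 5).
#' @param n_iterations Shuffled repetitions (default 100).
#' @param model A [classifier_spec()].
#' @param preprocess A [preprocess_config()].
#' @param repair_lambda `NULL` for no repair, else a repair amount in
#'   \[0, 1\].
#' @param base_seed Integer; iteration i uses seed `base_seed + i`, so the
#'   whole audit is a pure function of (cohort, config).
#' @return An object of class `harness_config`.
#' @export
harness_config <- function(n_folds = 5, n_iterations = 100,
                           model = classifier_spec("random_forest"),
                           preprocess = preprocess_config(),
                           repair_lambda = NULL, base_seed = 1L) {
  check_count(n_folds, "n_folds", min = 2)
  check_count(n_iterations, "n_iterations", min = 1)
  stopifnot(inherits(model, "classifier_spec"), inherits(preprocess, "preprocess_config"))
  if (!is.null(repair_lambda)) {
    if (!is.numeric(repair_lambda) || length(repair_lambda) != 1 ||
        is.na(repair_lambda) || repair_lambda < 0 || repair_lambda > 1) {
      stop_config("repair_lambda must be NULL or a single number in [0, 1]")
    }
  }
  check_count(base_seed, "base_seed", min = -.Machine$integer.max)
  structure(list(n_folds = as.integer(n_folds),
                 n_iterations = as.integer(n_iterations),
                 model = model, preprocess = preprocess,
                 repair_lambda = repair_lambda,
                 base_seed = as.integer(base_seed)),
            class = "harness_config")
}

# fold assignment stratified on the joint (label x group) cell, so every
# fold keeps both groups and both classes whenever counts allow; a global
# round-robin counter keeps fold sizes within 1 of each other
stratified_folds <- function(label, group, n_folds, order) {
  fold <- integer(length(label))
  cell <- interaction(label, group, drop = TRUE)
  counter <- 0L
  for (cl in levels(cell)) {
    idx <- order[cell[order] == cl]
    fold[idx] <- ((counter + seq_along(idx) - 1L) %% n_folds) + 1L
    counter <- counter + length(idx)
  }
  fold
}

#' Run one shuffled cross-validation iteration
#'
#' Shuffles the cohort with seed `base_seed + iteration`, assigns stratified
#' folds, and for each fold fits the entire chain — optional quantile
#' repair, then median imputation, standardization, SMOTE (training rows
#' only; held-out folds keep their original class ratio), PCA, and the
#' classifier — strictly on the training rows before predicting the
#' held-out fold. Out-of-fold predictions are pooled over all rows and
#' summarized in a fairness report.
#'
#' A fold whose training data lacks a class, or pooled predictions on which
#' a metric is undefined, mark the iteration as skipped (with the reason)
#' rather than failing the audit.
#'
#' @param cohort A labeled cohort with both groups and both classes.
#' @param config A [harness_config()].
#' @param iteration Iteration index (determines the shuffle seed).
#' @return An `iteration_result`: `iteration`, `skipped`, `reason`, and when
#'   not skipped the pooled `y_true`, `y_pred`, `group` and the
#'   `fairness_report`.
#' @export
run_iteration <- function(cohort, config, iteration) {
  stopifnot(inherits(cohort, "cohort"), inherits(config, "harness_config"))
  if (is.null(cohort$label)) stop_config("cohort must be labeled (see median_split_label)")
  if (length(unique(cohort$label)) < 2) stop_config("cohort must contain both classes")
  if (nlevels(droplevels(cohort$group)) < 2) stop_config("cohort must contain both groups")
  n <- nrow(cohort)
  K <- config$n_folds
  iter_seed <- config$base_seed + as.integer(iteration)
  seeds <- withr::with_seed(iter_seed, {
    order <- sample.int(n)
    sub <- sample.int(.Machine$integer.max - 1L, 2L * K)
    list(order = order, sub = sub)
  })
  fold <- stratified_folds(cohort$label, cohort$group, K, seeds$order)

  y_pred <- rep(NA_integer_, n)
  result <- tryCatch({
    for (k in seq_len(K)) {
      test_idx <- which(fold == k)
      train_idx <- which(fold != k)
      train_tab <- cohort[train_idx, , drop = FALSE]
      test_tab <- cohort[test_idx, , drop = FALSE]
      if (length(unique(train_tab$label)) < 2) {
        stop_config(sprintf("fold %d: training data lacks a class", k))
      }
      if (!is.null(config$repair_lambda)) {
        rep_out <- repair_pipeline_hook(train_tab, test_tab, config$repair_lambda)
        train_tab <- rep_out$train
        test_tab <- rep_out$test
      }
      pp_cfg <- config$preprocess
      pp_cfg$seed <- seeds$sub[2L * k - 1L]
      transform <- fit_preprocess(train_tab, pp_cfg)
      spec <- config$model
      spec$seed <- seeds$sub[2L * k]
      model <- train_classifier(spec, transform$train_X, transform$train_y)
      y_pred[test_idx] <- predict_classifier(model, apply_preprocess(transform, test_tab))
    }
    report <- fairness_report(cohort$label, y_pred, cohort$group,
                              privileged = attr(cohort, "privileged"))
    list(iteration = as.integer(iteration), skipped = FALSE, reason = NA_character_,
         y_true = cohort$label, y_pred = y_pred, group = cohort$group,
         report = report)
  }, fairaudit_config_error = function(e) {
    list(iteration = as.integer(iteration), skipped = TRUE,
         reason = conditionMessage(e))
  }, fairaudit_undefined_metric = function(e) {
    list(iteration = as.integer(iteration), skipped = TRUE,
         reason = conditionMessage(e))
  })
  structure(result, class = "iteration_result")
}

audit_metric_names <- c("delta_accuracy", "abs_delta_accuracy", "delta_tpr",
                        "delta_fpr", "spd", "disparate_impact", "ber",
                        "accuracy_overall", "accuracy_privileged",
                        "accuracy_unprivileged")

#' Run a full repeated-CV fairness audit
#'
#' Executes all iterations, collects per-iteration metrics, and aggregates
#' them as mean and SD across non-skipped iterations. The headline group
#' comparison — a two-tailed Welch t-test of privileged vs unprivileged
#' per-person correctness (each participant's correctness averaged over
#' iterations) — is included; participants, not iterations, are the
#' sampling units, because repeated CV on one cohort does not yield
#' independent replicates. Aborts if more than half the iterations are
#' skipped.
#'
#' @inheritParams run_iteration
#' @return An `audit_summary` with `metrics` (per-iteration matrix, one row
#'   per completed iteration), `means`, `sds`, `group_accuracy_test`
#'   (t-statistic and p-value), `n_skipped`, `skip_reasons`, `config`, and
#'   the cohort size `n`.
#' @export
run_audit <- function(cohort, config) {
  results <- lapply(seq_len(config$n_iterations),
                    function(i) run_iteration(cohort, config, i))
  skipped <- vapply(results, function(r) r$skipped, logical(1))
  if (mean(skipped) > 0.5) {
    stop_config(sprintf(
      "audit aborted: %d of %d iterations skipped (first reason: %s)",
      sum(skipped), length(results), results[[which(skipped)[1]]]$reason))
  }
  kept <- results[!skipped]
  metrics <- do.call(rbind, lapply(kept, function(r) {
    rep_ <- r$report
    c(delta_accuracy = rep_$delta_accuracy,
      abs_delta_accuracy = abs(rep_$delta_accuracy),
      delta_tpr = rep_$delta_tpr, delta_fpr = rep_$delta_fpr,
      spd = rep_$spd, disparate_impact = rep_$disparate_impact,
      ber = rep_$ber, accuracy_overall = rep_$accuracy_overall,
      accuracy_privileged = rep_$accuracy_privileged,
      accuracy_unprivileged = rep_$accuracy_unprivileged)
  }))
  # group accuracy comparison with participants as the sampling units:
  # per-person correctness averaged over iterations, privileged vs
  # unprivileged. Iterations of CV on one fixed cohort are not independent
  # replicates, so a t-test across the per-iteration accuracy vectors has
  # badly inflated type-I error; across people it is calibrated.
  correct <- Reduce(`+`, lapply(kept, function(r) as.integer(r$y_true == r$y_pred)))
  person_acc <- correct / length(kept)
  priv <- is_privileged(cohort)
  test <- tryCatch(
    t_test_two_tailed(person_acc[priv], person_acc[!priv]),
    fairaudit_config_error = function(e) list(statistic = NA_real_, p_value = NA_real_)
  )
  structure(list(
    metrics = metrics,
    means = colMeans(metrics),
    sds = if (nrow(metrics) > 1) apply(metrics, 2, stats::sd) else
      stats::setNames(rep(0, ncol(metrics)), colnames(metrics)),
    group_accuracy_test = test,
    n_skipped = sum(skipped),
    skip_reasons = vapply(results[skipped], function(r) r$reason, character(1)),
    config = config,
    n = nrow(cohort)
  ), class = "audit_summary")
}

#' @export
print.audit_summary <- function(x, ...) {
  m <- x$means; s <- x$sds
  cat(sprintf("<audit_summary> %s, %d x %d-fold CV on %d participants (%d skipped)\n",
              x$config$model$family, nrow(x$metrics), x$config$n_folds, x$n,
              x$n_skipped))
  if (!is.null(x$config$repair_lambda)) {
    cat(sprintf("  disparate impact remover: lambda = %.2f\n", x$config$repair_lambda))
  }
  cat(sprintf("  accuracy %.2f%% (SD %.2f) | privileged %.2f%% | unprivileged %.2f%% | t-test p = %.3g\n",
              m["accuracy_overall"], s["accuracy_overall"],
              m["accuracy_privileged"], m["accuracy_unprivileged"],
              x$group_accuracy_test$p_value))
  cat(sprintf("  |delta acc| %.2f | dTPR %.2f | dFPR %.2f | SPD %.2f | DI %.3f | BER %.3f\n",
              m["abs_delta_accuracy"], m["delta_tpr"], m["delta_fpr"],
              m["spd"], m["disparate_impact"], m["ber"]))
  invisible(x)
}

compare_metric_names <- c("delta_accuracy", "delta_tpr", "delta_fpr",
                          "spd", "disparate_impact", "ber")

#' Compare audits before and after bias mitigation
#'
#' Lines up the six fairness metrics of two audits of the same cohort and
#' model family (typically baseline vs repaired), reporting before/after
#' mean (SD), the difference of means, and a two-tailed Welch t-test on the
#' per-iteration vectors, plus the overall-accuracy cost of the repair.
#'
#' @param baseline,repaired `audit_summary` objects with equal iteration
#'   counts.
#' @return An `audit_comparison`: a data.frame with one row per metric and
#'   columns `metric`, `before_mean`, `before_sd`, `after_mean`, `after_sd`,
#'   `difference`, `p_value`; the accuracy cost (before minus after overall
#'   accuracy, percentage points) is in `attr(, "accuracy_cost")`.
#' @export
compare_before_after <- function(baseline, repaired) {
  stopifnot(inherits(baseline, "audit_summary"), inherits(repaired, "audit_summary"))
  if (nrow(baseline$metrics) != nrow(repaired$metrics)) {
    stop_config("audits have mismatched iteration counts")
  }
  if (baseline$config$model$family != repaired$config$model$family) {
    stop_config("audits use different model families")
  }
  rows <- lapply(compare_metric_names, function(mn) {
    a <- baseline$metrics[, mn]; b <- repaired$metrics[, mn]
    p <- if (identical(a, b)) 1 else t_test_two_tailed(a, b)$p_value
    data.frame(metric = mn,
               before_mean = mean(a), before_sd = stats::sd(a),
               after_mean = mean(b), after_sd = stats::sd(b),
               difference = mean(b) - mean(a), p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "accuracy_cost") <-
    baseline$means[["accuracy_overall"]] - repaired$means[["accuracy_overall"]]
  class(out) <- c("audit_comparison", "data.frame")
  out
}

#' Write an audit summary (or comparison) to JSON
#'
#' Serializes means, SDs, per-iteration metrics, the group t-test and the
#' run configuration — a run manifest sufficient to archive an audit.
#'
#' @param summary An `audit_summary`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_audit_summary <- function(summary, path) {
  stopifnot(inherits(summary, "audit_summary"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("fairaudit")),
    model = summary$config$model$family,
    hyperparameters = summary$config$model$hyperparameters,
    n_folds = summary$config$n_folds,
    n_iterations = summary$config$n_iterations,
    repair_lambda = summary$config$repair_lambda,
    base_seed = summary$config$base_seed,
    n_participants = summary$n,
    n_skipped = summary$n_skipped,
    skip_reasons = summary$skip_reasons,
    means = as.list(summary$means),
    sds = as.list(summary$sds),
    group_accuracy_test = summary$group_accuracy_test,
    metrics = as.data.frame(summary$metrics)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
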