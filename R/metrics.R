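#' Per-group confusion counts
#'
#' Tallies TP/FP/TN/FN separately for the privileged and unprivileged
#' groups; these eight counts are the sole input to every group-fairness
#' metric here. The favorable outcome is the positive label (1).
#'
#' @param y_true True 0/1 labels.
#' @param y_pred Predicted 0/1 labels.
#' @param group Group membership, a factor/vector with exactly two levels.
#' @param privileged The level of `group` regarded as privileged.
#' @return An object of class `grouped_confusion`: a list with components
#'   `privileged` and `unprivileged`, each holding `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_by_group <- function(y_true, y_pred, group, privileged) {
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred) || length(y_true) != length(group)) {
    stop_config("y_true, y_pred and group must have equal lengths")
  }
  if (!all(c(y_true, y_pred) %in% c(0L, 1L))) {
    stop_config("labels must be 0/1")
  }
  lv <- unique(as.character(group))
  if (length(lv) > 2) stop_config("group must have at most two observed levels")
  if (missing(privileged)) privileged <- sort(lv, decreasing = TRUE)[1]
  priv <- as.character(group) == privileged
  tally <- function(keep) {
    t <- y_true[keep]; p <- y_pred[keep]
    list(tp = sum(t == 1L & p == 1L), fp = sum(t == 0L & p == 1L),
         tn = sum(t == 0L & p == 0L), fn = sum(t == 1L & p == 0L))
  }
  structure(list(privileged = tally(priv), unprivileged = tally(!priv)),
            class = "grouped_confusion")
}

group_n <- function(g) g$tp + g$fp + g$tn + g$fn

require_nonempty <- function(conf) {
  for (side in c("privileged", "unprivileged")) {
    if (group_n(conf[[side]]) == 0) {
      stop_undefined_metric(sprintf("metric undefined: %s group is empty", side))
    }
  }
}

group_accuracy <- function(g) (g$tp + g$tn) / group_n(g)

#' Delta accuracy between groups
#'
#' Accuracy of the privileged group minus accuracy of the unprivileged
#' group, in percentage points; 0 is the ideal.
#'
#' @param conf A [confusion_by_group()] result.
#' @return Signed percentage points in \[-100, 100\].
#' @export
delta_accuracy <- function(conf) {
  require_nonempty(conf)
  100 * (group_accuracy(conf$privileged) - group_accuracy(conf$unprivileged))
}

#' Delta true-positive rate (equal opportunity gap)
#'
#' TPR of the privileged group minus TPR of the unprivileged group, in
#' percentage points: the gap in chances that a truly high-scoring person is
#' recognized as such, by group.
#'
#' @inheritParams delta_accuracy
#' @return Signed percentage points.
#' @export
delta_tpr <- function(conf) {
  rates <- lapply(conf[c("privileged", "unprivileged")], function(g) {
    if (g$tp + g$fn == 0) return(NA_real_)
    g$tp / (g$tp + g$fn)
  })
  if (anyNA(unlist(rates))) {
    side <- names(rates)[is.na(unlist(rates))][1]
    stop_undefined_metric(sprintf("delta TPR undefined: no positives in %s group", side))
  }
  100 * (rates$privileged - rates$unprivileged)
}

#' Delta false-positive rate
#'
#' FPR of the privileged group minus FPR of the unprivileged group, in
#' percentage points: the gap in chances that a truly low-scoring person is
#' nevertheless granted the favorable label, by group.
#'
#' @inheritParams delta_accuracy
#' @return Signed percentage points.
#' @export
delta_fpr <- function(conf) {
  rates <- lapply(conf[c("privileged", "unprivileged")], function(g) {
    if (g$fp + g$tn == 0) return(NA_real_)
    g$fp / (g$fp + g$tn)
  })
  if (anyNA(unlist(rates))) {
    side <- names(rates)[is.na(unlist(rates))][1]
    stop_undefined_metric(sprintf("delta FPR undefined: no negatives in %s group", side))
  }
  100 * (rates$privileged - rates$unprivileged)
}

positive_rate <- function(g) (g$tp + g$fp) / group_n(g)

#' Statistical parity difference
#'
#' Difference in favorable-outcome (positive prediction) probability between
#' the groups, in percentage points. Reported as privileged minus
#' unprivileged, so positive values mean the model favors the privileged
#' group; set `flip_sign = TRUE` for the opposite convention.
#'
#' @inheritParams delta_accuracy
#' @param flip_sign Report unprivileged minus privileged instead.
#' @return Signed percentage points.
#' @export
statistical_parity_difference <- function(conf, flip_sign = FALSE) {
  require_nonempty(conf)
  spd <- 100 * (positive_rate(conf$privileged) - positive_rate(conf$unprivileged))
  if (flip_sign) -spd else spd
}

#' Disparate impact ratio
#'
#' Ratio of the favorable-outcome probability of the unprivileged group to
#' that of the privileged group. 1.0 is the ideal; by the four-fifths
#' convention a value below 0.8 flags the model as biased.
#'
#' @inheritParams delta_accuracy
#' @return A nonnegative ratio with attribute `biased` (`TRUE` when < 0.8).
#' @export
disparate_impact <- function(conf) {
  require_nonempty(conf)
  p_priv <- positive_rate(conf$privileged)
  if (p_priv == 0) {
    stop_undefined_metric("disparate impact undefined: privileged positive rate is 0")
  }
  di <- positive_rate(conf$unprivileged) / p_priv
  attr(di, "biased") <- di < 0.8
  di
}

#' Balanced error rate
#'
#' Mean of the two group error rates, weighting each group equally
#' regardless of its size: a 100-row sample whose 90 privileged rows are all
#' classified correctly and whose 10 unprivileged rows are all wrong has
#' overall error rate 0.1 but balanced error rate (0 + 1) / 2 = 0.5.
#'
#' @inheritParams delta_accuracy
#' @return Proportion in \[0, 1\].
#' @export
balanced_error_rate <- function(conf) {
  require_nonempty(conf)
  err <- function(g) 1 - group_accuracy(g)
  (err(conf$privileged) + err(conf$unprivileged)) / 2
}

#' Overall (group-blind) error rate
#'
#' @inheritParams delta_accuracy
#' @return Proportion in \[0, 1\].
#' @export
overall_error_rate <- function(conf) {
  n <- group_n(conf$privileged) + group_n(conf$unprivileged)
  if (n < 1) stop_undefined_metric("error rate undefined on an empty sample")
  (conf$privileged$fp + conf$privileged$fn +
     conf$unprivileged$fp + conf$unprivileged$fn) / n
}

#' Two-sample two-tailed t-test
#'
#' Nonpaired two-tailed comparison of two samples of real values (e.g.,
#' per-iteration privileged vs unprivileged accuracies). Welch's unequal
#' variance form is the default; the pooled-variance form is exposed.
#'
#' @param a,b Numeric samples, each with at least 2 values.
#' @param var_equal Use the pooled-variance (Student) form.
#' @return List with `statistic` (t) and `p_value`.
#' @export
t_test_two_tailed <- function(a, b, var_equal = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) {
    stop_config("each sample must contain at least 2 values")
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      return(list(statistic = 0, p_value = 1))
    }
    stop_config("degenerate samples: both have zero variance")
  }
  tt <- stats::t.test(a, b, alternative = "two.sided", var.equal = var_equal)
  list(statistic = unname(tt$statistic), p_value = unname(tt$p.value))
}

#' Full fairness report for one evaluation
#'
#' Computes the five group-bias metrics plus the balanced error rate and
#' per-group accuracies from pooled predictions.
#'
#' @inheritParams confusion_by_group
#' @return An object of class `fairness_report`: a list with
#'   `delta_accuracy`, `delta_tpr`, `delta_fpr`, `spd` (all signed
#'   percentage points), `disparate_impact` (ratio), `ber` (proportion),
#'   `accuracy_overall`, `accuracy_privileged`, `accuracy_unprivileged`
#'   (percentages).
#' @export
fairness_report <- function(y_true, y_pred, group, privileged) {
  conf <- confusion_by_group(y_true, y_pred, group, privileged)
  structure(list(
    delta_accuracy = delta_accuracy(conf),
    delta_tpr = delta_tpr(conf),
    delta_fpr = delta_fpr(conf),
    spd = statistical_parity_difference(conf),
    disparate_impact = as.numeric(disparate_impact(conf)),
    ber = balanced_error_rate(conf),
    accuracy_overall = 100 * (1 - overall_error_rate(conf)),
    accuracy_privileged = 100 * group_accuracy(conf$privileged),
    accuracy_unprivileged = 100 * group_accuracy(conf$unprivileged)
  ), class = "fairness_report")
}

#' @export
print.fairness_report <- function(x, ...) {
  cat("<fairness_report>\n")
  cat(sprintf("  accuracy: overall %.2f%%, privileged %.2f%%, unprivileged %.2f%%\n",
              x$accuracy_overall, x$accuracy_privileged, x$accuracy_unprivileged))
  cat(sprintf("  delta accuracy %.2f pp | dTPR %.2f pp | dFPR %.2f pp | SPD %.2f pp\n",
              x$delta_accuracy, x$delta_tpr, x$delta_fpr, x$spd))
  cat(sprintf("  disparate impact %.3f%s | BER %.3f\n", x$disparate_impact,
              if (x$disparate_impact < 0.8) " (biased, < 0.8)" else "", x$ber))
  invisible(x)
}
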