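conf_from <- function(priv, unpriv) {
  structure(list(privileged = priv, unprivileged = unpriv),
            class = "grouped_confusion")
}

test_that("grouped confusion counts partition the sample", {
  conf <- confusion_by_group(c(1, 0), c(1, 0), c("man", "woman"), "man")
  expect_equal(conf$privileged, list(tp = 1L, fp = 0L, tn = 0L, fn = 0L))
  expect_equal(conf$unprivileged, list(tp = 0L, fp = 0L, tn = 1L, fn = 0L))
  # all predictions wrong: no TP or TN anywhere
  conf2 <- confusion_by_group(c(1, 0, 1, 0), c(0, 1, 0, 1),
                              c("man", "man", "woman", "woman"), "man")
  expect_equal(conf2$privileged$tp + conf2$privileged$tn, 0)
  expect_equal(conf2$unprivileged$tp + conf2$unprivileged$tn, 0)
  expect_error(confusion_by_group(c(1, 0), c(1), c("a", "b")),
               class = "fairaudit_config_error")
  expect_error(confusion_by_group(c(1, 0, 1), c(1, 0, 1), c("a", "b", "c")),
               class = "fairaudit_config_error")
})

test_that("hand-counted examples for the difference metrics", {
  # privileged 9/10 correct, unprivileged 6/10 correct
  conf <- conf_from(list(tp = 9, fp = 0, tn = 0, fn = 1),
                    list(tp = 3, fp = 1, tn = 3, fn = 3))
  expect_equal(delta_accuracy(conf), 30)
  # TP/FN 8/2 vs 3/7
  conf <- conf_from(list(tp = 8, fp = 0, tn = 5, fn = 2),
                    list(tp = 3, fp = 0, tn = 5, fn = 7))
  expect_equal(delta_tpr(conf), 50)
  # 14/20 vs 6/15 predicted positive
  conf <- conf_from(list(tp = 10, fp = 4, tn = 4, fn = 2),
                    list(tp = 4, fp = 2, tn = 6, fn = 3))
  expect_equal(statistical_parity_difference(conf), 30)
  expect_equal(statistical_parity_difference(conf, flip_sign = TRUE), -30)
  # unpriv rate 0.40, priv rate 0.70
  conf <- conf_from(list(tp = 5, fp = 2, tn = 2, fn = 1),
                    list(tp = 3, fp = 1, tn = 4, fn = 2))
  di <- disparate_impact(conf)
  expect_equal(as.numeric(di), 0.4 / 0.7, tolerance = 1e-12)
  expect_true(attr(di, "biased"))
})

test_that("balanced and overall error rates follow their definitions", {
  # 90 privileged all right, 10 unprivileged all wrong
  conf <- confusion_by_group(
    y_true = c(rep(1, 45), rep(0, 45), rep(1, 10)),
    y_pred = c(rep(1, 45), rep(0, 45), rep(0, 10)),
    group = c(rep("man", 90), rep("woman", 10)), privileged = "man")
  expect_identical(overall_error_rate(conf), 0.1)
  expect_identical(balanced_error_rate(conf), 0.5)
  # err 0.2 and 0.4 average to 0.3
  conf <- conf_from(list(tp = 4, fp = 1, tn = 4, fn = 1),
                    list(tp = 3, fp = 2, tn = 3, fn = 2))
  expect_equal(balanced_error_rate(conf), 0.3, tolerance = 1e-12)
  expect_equal(overall_error_rate(conf), 6 / 20, tolerance = 1e-12)
  # perfection
  conf <- conf_from(list(tp = 5, fp = 0, tn = 5, fn = 0),
                    list(tp = 5, fp = 0, tn = 5, fn = 0))
  expect_equal(balanced_error_rate(conf), 0)
  expect_equal(overall_error_rate(conf), 0)
})

test_that("every metric matches the brute-force per-row oracle", {
  for (s in 1:300) {
    inst <- random_prediction_instance(s)
    conf <- confusion_by_group(inst$y_true, inst$y_pred, inst$group, "man")
    o <- oracle_metrics(inst$y_true, inst$y_pred, inst$group, "man")
    expect_equal(delta_accuracy(conf), o$delta_accuracy, tolerance = 1e-12)
    expect_equal(statistical_parity_difference(conf), o$spd, tolerance = 1e-12)
    expect_equal(balanced_error_rate(conf), o$ber, tolerance = 1e-12)
    expect_equal(overall_error_rate(conf), o$overall_error, tolerance = 1e-12)
    if (!is.na(o$delta_tpr)) {
      expect_equal(delta_tpr(conf), o$delta_tpr, tolerance = 1e-12)
    }
    if (!is.na(o$delta_fpr)) {
      expect_equal(delta_fpr(conf), o$delta_fpr, tolerance = 1e-12)
    }
    if (is.finite(o$disparate_impact)) {
      expect_equal(as.numeric(disparate_impact(conf)), o$disparate_impact,
                   tolerance = 1e-12)
    }
  }
})

test_that("swapping the privileged level negates deltas and inverts the ratio", {
  for (s in 1:40) {
    inst <- random_prediction_instance(s + 5000)
    a <- confusion_by_group(inst$y_true, inst$y_pred, inst$group, "man")
    b <- confusion_by_group(inst$y_true, inst$y_pred, inst$group, "woman")
    expect_equal(delta_accuracy(a), -delta_accuracy(b), tolerance = 1e-12)
    expect_equal(statistical_parity_difference(a),
                 -statistical_parity_difference(b), tolerance = 1e-12)
    da <- tryCatch(as.numeric(disparate_impact(a)), error = function(e) NA)
    db <- tryCatch(as.numeric(disparate_impact(b)), error = function(e) NA)
    if (!anyNA(c(da, db)) && da > 0) {
      expect_equal(da, 1 / db, tolerance = 1e-10)
    }
  }
})

test_that("BER equals the overall error rate for equal-size, equal-error groups", {
  conf <- conf_from(list(tp = 6, fp = 2, tn = 10, fn = 2),
                    list(tp = 8, fp = 3, tn = 8, fn = 1))
  expect_equal(balanced_error_rate(conf), overall_error_rate(conf),
               tolerance = 1e-12)
})

test_that("parity in rates is equivalent between the ratio and the difference", {
  for (s in 1:40) {
    inst <- random_prediction_instance(s + 9000)
    conf <- confusion_by_group(inst$y_true, inst$y_pred, inst$group, "man")
    spd <- statistical_parity_difference(conf)
    di <- tryCatch(as.numeric(disparate_impact(conf)), error = function(e) NA)
    if (!is.na(di) && di > 0) {
      expect_equal(abs(spd) < 1e-12, abs(di - 1) < 1e-12)
    }
  }
})

test_that("undefined metrics raise structured errors, not NaN", {
  one_group <- confusion_by_group(c(1, 0), c(1, 0), c("man", "man"), "man")
  expect_error(delta_accuracy(one_group), class = "fairaudit_undefined_metric")
  no_pos <- confusion_by_group(c(0, 0, 1), c(0, 0, 1),
                               c("man", "woman", "man"), "man")
  expect_error(delta_tpr(no_pos), "woman|unprivileged",
               class = "fairaudit_undefined_metric")
  no_predpos <- confusion_by_group(c(1, 1), c(0, 0), c("man", "woman"), "man")
  expect_error(disparate_impact(no_predpos), class = "fairaudit_undefined_metric")
})

test_that("the two-tailed t-test matches textbook Welch and pooled formulas", {
  expect_equal(t_test_two_tailed(c(1, 2, 3), c(3, 2, 1)),
               list(statistic = 0, p_value = 1))
  expect_identical(t_test_two_tailed(c(2, 2, 2), c(2, 2, 2)),
                   list(statistic = 0, p_value = 1))
  expect_error(t_test_two_tailed(c(1, 1), c(2, 2)),
               class = "fairaudit_config_error")
  expect_error(t_test_two_tailed(1, c(1, 2)), class = "fairaudit_config_error")

  a <- c(85, 87, 86); b <- c(70, 72, 71)
  out <- t_test_two_tailed(a, b)
  expect_lt(out$p_value, 0.01)
  # Welch oracle, written out from the definition
  se2 <- stats::var(a) / 3 + stats::var(b) / 3
  tt <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((stats::var(a) / 3)^2 / 2 + (stats::var(b) / 3)^2 / 2)
  expect_equal(out$statistic, tt, tolerance = 1e-12)
  expect_equal(out$p_value, 2 * stats::pt(-abs(tt), df), tolerance = 1e-12)
  # pooled-variance oracle
  outp <- t_test_two_tailed(a, b, var_equal = TRUE)
  sp2 <- (2 * stats::var(a) + 2 * stats::var(b)) / 4
  tp <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(outp$statistic, tp, tolerance = 1e-12)
  expect_equal(outp$p_value, 2 * stats::pt(-abs(tp), 4), tolerance = 1e-12)
})

test_that("fairness reports bundle all metrics coherently", {
  inst <- random_prediction_instance(77)
  rep_ <- fairness_report(inst$y_true, inst$y_pred, inst$group, "man")
  o <- oracle_metrics(inst$y_true, inst$y_pred, inst$group, "man")
  expect_equal(rep_$delta_accuracy, o$delta_accuracy, tolerance = 1e-12)
  expect_equal(rep_$ber, o$ber, tolerance = 1e-12)
  expect_equal(rep_$accuracy_overall, 100 * (1 - o$overall_error), tolerance = 1e-12)
})
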