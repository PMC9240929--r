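# shared fixtures and independent oracles, all built in code

biased_cohort <- function(seed, n = 200) {
  median_split_label(generate_cohort(synthetic_config(
    n_participants = n, minority_fraction = 0.38,
    group_shift = 0.6, legacy_strength = 0.7, seed = seed
  )))
}

null_cohort <- function(seed, n = 200) {
  median_split_label(generate_cohort(synthetic_config(
    n_participants = n, minority_fraction = 0.38,
    group_shift = 0, legacy_strength = 0, seed = seed
  )))
}

# a cohort whose label is perfectly recoverable from the features and whose
# groups are balanced across labels
separable_cohort <- function(n = 60, seed = 1) {
  withr::with_seed(seed, {
    label <- rep(c(0L, 1L), each = n / 2)
    x1 <- label * 10 + stats::rnorm(n, sd = 0.1)
    x2 <- -label * 10 + stats::rnorm(n, sd = 0.1)
    grp <- rep(c("man", "woman"), n / 2)
  })
  as_cohort(data.frame(
    id = sprintf("S%03d", seq_len(n)), group = grp,
    feat_1 = x1, feat_2 = x2,
    score = 50 + label * 20, label = label,
    stringsAsFactors = FALSE
  ), privileged = "man")
}

# brute-force fairness metrics recomputed per row, independent of the
# grouped-confusion path
oracle_metrics <- function(y_true, y_pred, group, privileged) {
  priv <- as.character(group) == privileged
  acc <- function(keep) mean(y_pred[keep] == y_true[keep])
  tpr <- function(keep) {
    pos <- keep & y_true == 1
    if (!any(pos)) return(NA_real_)
    mean(y_pred[pos] == 1)
  }
  fpr <- function(keep) {
    neg <- keep & y_true == 0
    if (!any(neg)) return(NA_real_)
    mean(y_pred[neg] == 1)
  }
  prate <- function(keep) mean(y_pred[keep] == 1)
  list(
    delta_accuracy = 100 * (acc(priv) - acc(!priv)),
    delta_tpr = 100 * (tpr(priv) - tpr(!priv)),
    delta_fpr = 100 * (fpr(priv) - fpr(!priv)),
    spd = 100 * (prate(priv) - prate(!priv)),
    disparate_impact = prate(!priv) / prate(priv),
    ber = ((1 - acc(priv)) + (1 - acc(!priv))) / 2,
    overall_error = mean(y_pred != y_true)
  )
}

random_prediction_instance <- function(seed, n_max = 200) {
  withr::with_seed(seed, {
    n <- sample(10:n_max, 1)
    list(
      y_true = sample(0:1, n, replace = TRUE),
      y_pred = sample(0:1, n, replace = TRUE),
      group = sample(c("man", "woman"), n, replace = TRUE,
                     prob = c(0.62, 0.38))
    )
  })
}

# direct empirical-CDF scan for the two-sample KS statistic
ks_statistic <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  Fa <- vapply(grid, function(t) mean(a <= t), numeric(1))
  Fb <- vapply(grid, function(t) mean(b <= t), numeric(1))
  max(abs(Fa - Fb))
}

# verify each synthetic SMOTE row lies on a segment between a minority
# point and one of its k nearest minority neighbors (brute-force search)
on_neighbor_segment <- function(s, minority, k, tol = 1e-8) {
  m <- nrow(minority)
  d2 <- as.matrix(stats::dist(minority))^2
  diag(d2) <- Inf
  for (i in seq_len(m)) {
    nbrs <- order(d2[i, ])[seq_len(min(k, m - 1))]
    for (j in nbrs) {
      v <- minority[j, ] - minority[i, ]
      w <- s - minority[i, ]
      denom <- sum(v^2)
      if (denom == 0) next
      u <- sum(w * v) / denom
      if (u >= -tol && u <= 1 + tol &&
          sqrt(sum((w - u * v)^2)) < tol * (1 + sqrt(denom))) {
        return(TRUE)
      }
    }
  }
  FALSE
}
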