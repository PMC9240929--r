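#' Fit a disparate impact remover (quantile feature repair)
#'
#' For each feature, stores each group's sorted training values. The repair
#' target for a value at within-group percentile p is the cross-group median
#' of the per-group empirical p-quantiles — with two groups, the midpoint of
#' the two group quantile curves. A man at the 80th percentile of men and a
#' woman at the 80th percentile of women are thereby mapped to the same
#' repaired value, removing the marginal group signal from every feature
#' while preserving within-group ranking.
#'
#' Conventions: the empirical CDF is `F_g(x) = #(fit values <= x) / n_g`;
#' quantiles are the type-1 (left-continuous inverse) empirical quantiles of
#' the stored values, evaluated exactly at the requested probability (no
#' grid interpolation); probabilities of out-of-range values clamp to
#' \[0, 1\], i.e. to the group minimum/maximum.
#'
#' @param train A cohort table with both group levels present, each with at
#'   least 2 members; missing feature values are ignored when fitting.
#' @param lambda Repair amount in \[0, 1\]: 0 is the identity, 1 moves every
#'   value fully onto the target quantile curve; intermediate values give
#'   partial repairs.
#' @return An object of class `repair_model`.
#' @export
fit_repair <- function(train, lambda = 1) {
  stopifnot(inherits(train, "cohort"))
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop_config("lambda must be a single number in [0, 1]")
  }
  counts <- table(train$group)
  if (any(counts < 2)) {
    stop_config(paste("each group needs >= 2 members to fit a repair; got",
                      paste(sprintf("%s=%d", names(counts), counts), collapse = ", ")))
  }
  fcols <- feature_names(train)
  levels_g <- levels(train$group)
  per_feature <- lapply(fcols, function(fc) {
    vals <- lapply(levels_g, function(g) {
      v <- train[[fc]][train$group == g]
      sort(v[!is.na(v)])
    })
    names(vals) <- levels_g
    if (any(lengths(vals) < 2)) {
      stop_config(sprintf("feature %s has < 2 non-missing values in a group", fc))
    }
    vals
  })
  names(per_feature) <- fcols
  structure(
    list(per_feature = per_feature, lambda = lambda,
         group_levels = levels_g, privileged = attr(train, "privileged")),
    class = "repair_model"
  )
}

# type-1 empirical quantile of sorted values at probabilities p (clamped)
quantile_type1 <- function(sorted_vals, p) {
  n <- length(sorted_vals)
  idx <- pmin(pmax(ceiling(pmin(pmax(p, 0), 1) * n), 1L), n)
  sorted_vals[idx]
}

# target quantile curve: median across groups of the per-group quantiles
repair_target <- function(group_vals, p) {
  q <- vapply(group_vals, quantile_type1, numeric(length(p)), p = p)
  if (length(p) == 1) q <- matrix(q, nrow = 1)
  apply(q, 1, stats::median)
}

#' Apply a fitted repair to a cohort
#'
#' Each value x of feature f in group g becomes
#' `(1 - lambda) * x + lambda * qbar(F_g(x))`, where `F_g` is g's empirical
#' CDF from the fitting data and `qbar` the cross-group median quantile
#' curve. Groups, scores and labels are untouched; missing cells stay
#' missing; within-group rank order of every feature is preserved for all
#' lambda.
#'
#' @param model A [fit_repair()] result.
#' @param table A cohort table with the fitted features and group levels.
#' @return The repaired cohort.
#' @export
apply_repair <- function(model, table) {
  stopifnot(inherits(model, "repair_model"), inherits(table, "cohort"))
  if (nrow(table) == 0) return(table)
  unseen <- setdiff(levels(droplevels(table$group)), model$group_levels)
  if (length(unseen) > 0) {
    stop_config(paste("unseen group level(s):", paste(unseen, collapse = ", ")))
  }
  lambda <- model$lambda
  if (lambda == 0) return(table)
  fcols <- names(model$per_feature)
  missing_f <- setdiff(fcols, names(table))
  if (length(missing_f) > 0) {
    stop_config(paste("table lacks fitted feature(s):", paste(missing_f, collapse = ", ")))
  }
  for (fc in fcols) {
    group_vals <- model$per_feature[[fc]]
    for (g in model$group_levels) {
      rows <- which(table$group == g & !is.na(table[[fc]]))
      if (length(rows) == 0) next
      x <- table[[fc]][rows]
      fit_sorted <- group_vals[[g]]
      p <- findInterval(x, fit_sorted) / length(fit_sorted)  # ecdf, clamps below min to 0
      target <- repair_target(group_vals, p)
      table[[fc]][rows] <- (1 - lambda) * x + lambda * target
    }
  }
  table
}

#' Repair train and test tables with a train-fitted model
#'
#' Fits the quantile repair on the training rows only and applies it to
#' both tables, the leakage-free way to use a preprocessing-only mitigation
#' inside cross-validation. The downstream classifier is untouched.
#'
#' @param train,test Cohort tables sharing schema and group levels (`test`
#'   may be empty).
#' @inheritParams fit_repair
#' @return List with `train` and `test` repaired cohorts and the `model`.
#' @export
repair_pipeline_hook <- function(train, test, lambda = 1) {
  model <- fit_repair(train, lambda = lambda)
  list(train = apply_repair(model, train),
       test = apply_repair(model, test),
       model = model)
}

#' Serialize / restore a repair model as JSON
#'
#' @param model A `repair_model`.
#' @param path File path.
#' @return `write_repair_model` returns `path` invisibly;
#'   `read_repair_model` returns the restored `repair_model`.
#' @export
write_repair_model <- function(model, path) {
  stopifnot(inherits(model, "repair_model"))
  out <- unclass(model)
  # quantile values as %.17g strings: the empirical CDF is discontinuous at
  # the stored points, so the round-trip must be bit-exact
  out$per_feature <- lapply(out$per_feature, function(f) {
    lapply(f, function(v) sprintf("%.17g", v))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_repair_model
#' @export
read_repair_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$per_feature <- lapply(x$per_feature, function(f) lapply(f, as.numeric))
  structure(x, class = "repair_model")
}
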