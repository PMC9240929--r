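#' Per-model accuracy grid
#'
#' Renders one row per classifier family: overall, privileged-group and
#' unprivileged-group accuracy as "mean (SD)", the mean absolute
#' across-group delta, and the p-value of the two-tailed t-test comparing
#' per-iteration group accuracies. Percentages are printed to 2 decimals;
#' every number is read straight out of the audit summaries, nothing is
#' recomputed at render time.
#'
#' @param summaries List of `audit_summary` objects with distinct model
#'   families.
#' @return A character data.frame with columns `model`,
#'   `overall_accuracy`, `privileged_accuracy`, `unprivileged_accuracy`,
#'   `delta_accuracy`, `p_value`.
#' @export
render_model_grid <- function(summaries) {
  if (inherits(summaries, "audit_summary")) summaries <- list(summaries)
  stopifnot(length(summaries) >= 1)
  families <- vapply(summaries, function(s) s$config$model$family, character(1))
  if (anyDuplicated(families)) {
    stop_config("duplicate model families in the grid")
  }
  fmt <- function(m, s) sprintf("%.2f (%.2f)", m, s)
  rows <- lapply(summaries, function(s) {
    data.frame(
      model = s$config$model$family,
      overall_accuracy = fmt(s$means["accuracy_overall"], s$sds["accuracy_overall"]),
      privileged_accuracy = fmt(s$means["accuracy_privileged"], s$sds["accuracy_privileged"]),
      unprivileged_accuracy = fmt(s$means["accuracy_unprivileged"], s$sds["accuracy_unprivileged"]),
      delta_accuracy = fmt(s$means["abs_delta_accuracy"], s$sds["abs_delta_accuracy"]),
      p_value = format_p(s$group_accuracy_test$p_value),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Bias-metric table with ideal scores
#'
#' Renders the six fairness metrics of one audit against their ideal
#' values: 0 for the four difference metrics (percentage points) and the
#' balanced error rate, 1.0 for the disparate impact ratio. Differences are
#' shown both signed and absolute; ratios are printed to 3 decimals.
#'
#' @param summary An `audit_summary`.
#' @return A character data.frame with columns `metric`, `observed`
#'   ("mean (SD)"), `observed_absolute`, `ideal`.
#' @export
render_bias_table <- function(summary) {
  stopifnot(inherits(summary, "audit_summary"))
  m <- summary$means; s <- summary$sds
  spec <- list(
    list("Delta accuracy (%)", "delta_accuracy", 2, "0"),
    list("Delta true positive rate (%)", "delta_tpr", 2, "0"),
    list("Delta false positive rate (%)", "delta_fpr", 2, "0"),
    list("Statistical parity difference (%)", "spd", 2, "0"),
    list("Disparate impact", "disparate_impact", 3, "1.0"),
    list("Balanced error rate", "ber", 3, "0")
  )
  rows <- lapply(spec, function(r) {
    digits <- r[[3]]
    col <- summary$metrics[, r[[2]]]
    data.frame(
      metric = r[[1]],
      observed = sprintf(paste0("%.", digits, "f (%.", digits, "f)"),
                         m[r[[2]]], s[r[[2]]]),
      observed_absolute = sprintf(paste0("%.", digits, "f"), mean(abs(col))),
      ideal = r[[4]],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Write a rendered table as CSV or JSON
#'
#' Plain serialization helpers; rendering is lossless and idempotent, so a
#' CSV round-trip reproduces the table exactly.
#'
#' @param table A data.frame from [render_model_grid()],
#'   [render_bias_table()] or [compare_before_after()].
#' @param path Output path; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_report_table <- function(table, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.data.frame(table), path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  }
  invisible(path)
}

format_p <- function(p) {
  if (is.na(p)) return("NA")
  if (p < 0.001) return("<.001")
  sub("^0", "", sprintf("%.3f", p))
}
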