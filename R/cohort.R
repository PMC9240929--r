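#' Configuration for the synthetic cohort generator
#'
#' Describes a small mobile-sensing cohort: `n_participants` people, a binary
#' protected attribute (gender) with a designated privileged level, a block of
#' numeric phone-usage features, and a continuous mental-health score.
#' Two knobs induce bias on purpose:
#'
#' * `group_shift` — location shift (in feature-SD units) of the privileged
#'   group's feature means relative to the minority group, reflecting that
#'   phone-use patterns differ by gender. It makes group membership
#'   recoverable from the features, the indirect pathway a disparate impact
#'   remover targets.
#' * `legacy_strength` — "negative legacy": a downward offset of the minority
#'   group's latent mental-health index, so the minority is under-represented
#'   among high (favorable) labels. At `legacy_strength = 0` the label is
#'   independent of group in expectation, whatever `group_shift` is, because
#'   the score is built from the shared latent factors, not the shifted
#'   observed features.
#'
#' Features are `n_features` noisy linear readouts of a 5-dimensional latent
#' Gaussian, so a rank-5 principal subspace carries essentially all feature
#' variance.
#'
#' @param n_participants Number of rows (default 55, a typical small
#'   field-study cohort).
#' @param minority_fraction Expected share of the unprivileged group, in
#'   (0, 1). Default 21/55.
#' @param n_features Number of phone-usage feature columns (default 10).
#' @param group_shift Per-feature mean shift between groups, in feature-SD
#'   units (default 0).
#' @param legacy_strength In \[0, 1\]; scales the minority score deficit
#'   (default 0).
#' @param noise_sd Standard deviation of the score noise on the latent-index
#'   scale (default 0.3, i.e. a measurement of roughly 0.9 reliability).
#' @param seed Integer RNG seed; the generated cohort is a pure function of
#'   this configuration.
#' @return An object of class `synthetic_config`.
#' @seealso [generate_cohort()]
#' @export
synthetic_config <- function(n_participants = 55,
                             minority_fraction = 21 / 55,
                             n_features = 10,
                             group_shift = 0,
                             legacy_strength = 0,
                             noise_sd = 0.3,
                             seed = 1L) {
  check_count(n_participants, "n_participants", min = 10)
  if (!is.numeric(minority_fraction) || length(minority_fraction) != 1 ||
      is.na(minority_fraction) || minority_fraction <= 0 || minority_fraction >= 1) {
    stop_config("minority_fraction must be a single number in (0, 1)")
  }
  check_count(n_features, "n_features", min = 1)
  if (!is.numeric(group_shift) || length(group_shift) != 1 || is.na(group_shift)) {
    stop_config("group_shift must be a single finite number")
  }
  if (!is.numeric(legacy_strength) || length(legacy_strength) != 1 ||
      is.na(legacy_strength) || legacy_strength < 0 || legacy_strength > 1) {
    stop_config("legacy_strength must be a single number in [0, 1]")
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || is.na(noise_sd) || noise_sd < 0) {
    stop_config("noise_sd must be a single number >= 0")
  }
  check_count(seed, "seed", min = -.Machine$integer.max)
  structure(
    list(
      n_participants = as.integer(n_participants),
      minority_fraction = minority_fraction,
      n_features = as.integer(n_features),
      group_shift = group_shift,
      legacy_strength = legacy_strength,
      noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

# latent dimensionality of the feature model; fixed so that PCA with 5
# components captures >99% of feature variance on generated cohorts
LATENT_DIM <- 5L

# score-scale constants: the latent index has SD ~1; scores are mapped onto a
# Mental Health Inventory-like 0-100 scale. The minority legacy offset at
# legacy_strength = 1 equals half a latent-index SD.
SCORE_CENTER <- 68
SCORE_SCALE <- 12
LEGACY_OFFSET_SD <- 0.5

# measurement noise on each feature, small relative to the unit-variance
# latent signal so the feature block is effectively rank LATENT_DIM
FEATURE_NOISE_SD <- 0.05

# composition of the gender feature shift: a fraction of its magnitude runs
# along the score-readout direction (phone-use differences that mimic poor
# mental health, confounding the apparent severity of the minority group),
# the rest along an orthogonal "style" direction carrying no health signal
SHIFT_CONFOUND_WEIGHT <- 0.9

#' Generate a synthetic phone-sensing cohort
#'
#' Draws a cohort with the structure described in [synthetic_config()]:
#' group membership is Bernoulli(`minority_fraction`) for the unprivileged
#' level, features are linear readouts of a shared 5-dimensional latent with
#' a `group_shift` mean offset for the privileged group, and the
#' mental-health score is a noisy monotone (linear) function of the latent
#' factors minus a `legacy_strength`-scaled offset for the minority group.
#' No labels are assigned; see [median_split_label()].
#'
#' @param config A [synthetic_config()].
#' @return A `cohort` data.frame with columns `id`, `group` (factor with
#'   levels `"woman"`, `"man"`; privileged level `"man"`), `feat_1` ...
#'   `feat_k`, and `score`. The privileged level is stored in
#'   `attr(, "privileged")`.
#' @examples
#' cohort <- generate_cohort(synthetic_config(seed = 7))
#' table(cohort$group)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    stop_config("config must be a synthetic_config object")
  }
  n <- config$n_participants
  k <- config$n_features
  withr::with_seed(config$seed, {
    minority <- stats::rbinom(n, 1L, config$minority_fraction)
    # loading matrix drawn once per seed; columns scaled so each feature has
    # unit latent variance in expectation, making group_shift an effect size
    loadings <- matrix(stats::rnorm(k * LATENT_DIM, sd = 1 / sqrt(LATENT_DIM)),
                       nrow = LATENT_DIM, ncol = k)
    beta <- stats::rnorm(LATENT_DIM)
    beta <- beta / sqrt(sum(beta^2))
    z <- matrix(stats::rnorm(n * LATENT_DIM), nrow = n)
    features <- z %*% loadings +
      matrix(stats::rnorm(n * k, sd = FEATURE_NOISE_SD), nrow = n)
    if (config$group_shift != 0) {
      # the minority group's features shift downward along a mix of the
      # score-readout direction (apparent-severity confound) and an
      # orthogonal style direction; total per-feature RMS shift equals
      # group_shift in feature-SD units
      u <- drop(beta %*% loadings)
      u <- u / sqrt(sum(u^2))
      # style direction: outside the span of all latent readouts, so it
      # carries no health signal at all
      Q <- qr.Q(qr(t(loadings)))
      v <- rep(1, k) - drop(Q %*% crossprod(Q, rep(1, k)))
      w <- SHIFT_CONFOUND_WEIGHT
      if (sqrt(sum(v^2)) > 1e-8) {
        v <- v / sqrt(sum(v^2))
      } else {
        v <- rep(0, k)
        w <- 1
      }
      shift_vec <- config$group_shift * sqrt(k) * (w * u + sqrt(1 - w^2) * v)
      features[minority == 1L, ] <- sweep(features[minority == 1L, , drop = FALSE],
                                          2, shift_vec, "-")
    }
    index <- drop(z %*% beta) +
      stats::rnorm(n, sd = config$noise_sd) -
      config$legacy_strength * LEGACY_OFFSET_SD * minority
    score <- SCORE_CENTER + SCORE_SCALE * index
  })
  colnames(features) <- paste0("feat_", seq_len(k))
  cohort <- data.frame(
    id = sprintf("P%03d", seq_len(n)),
    group = factor(ifelse(minority == 1L, "woman", "man"),
                   levels = c("woman", "man")),
    features,
    score = score,
    stringsAsFactors = FALSE
  )
  as_cohort(cohort, privileged = "man")
}

#' Construct a cohort table from a data.frame
#'
#' Validates the cohort contract: unique `id`, a binary `group` column,
#' numeric `feat_*` columns (finite or `NA`), a numeric `score`, and an
#' optional binary `label`.
#'
#' @param x A data.frame with columns `id`, `group`, `feat_1` ... `feat_k`,
#'   `score`, and optionally `label`.
#' @param privileged The level of `group` regarded as privileged.
#' @return `x` with class `cohort` and the privileged level attached.
#' @export
as_cohort <- function(x, privileged) {
  stopifnot(is.data.frame(x))
  required <- c("id", "group", "score")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop_config(paste("cohort is missing columns:",
                      paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(x$id)) stop_config("cohort ids must be unique")
  x$group <- as.factor(x$group)
  x$group <- droplevels(x$group)
  if (nlevels(x$group) != 2) {
    stop_config("group must take exactly two levels")
  }
  if (!privileged %in% levels(x$group)) {
    stop_config(sprintf("privileged level '%s' not found among group levels", privileged))
  }
  fcols <- feature_names(x)
  if (length(fcols) == 0) stop_config("cohort has no feat_* columns")
  for (fc in fcols) {
    if (!is.numeric(x[[fc]])) stop_config(sprintf("feature %s is not numeric", fc))
    bad <- !is.na(x[[fc]]) & !is.finite(x[[fc]])
    if (any(bad)) stop_config(sprintf("feature %s contains non-finite values", fc))
  }
  if (!is.null(x$label)) {
    lab <- x$label[!is.na(x$label)]
    if (!all(lab %in% c(0, 1))) stop_config("label must be 0/1 when present")
    x$label <- as.integer(x$label)
  }
  attr(x, "privileged") <- privileged
  class(x) <- unique(c("cohort", class(x)))
  x
}

#' @export
`[.cohort` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "privileged") <- attr(x, "privileged")
    class(out) <- unique(c("cohort", class(out)))
  }
  out
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d participants, %d features, privileged group: %s\n",
              nrow(x), length(feature_names(x)), attr(x, "privileged")))
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s=%d", levels(x$group), tabulate(x$group, nlevels(x$group))),
                    collapse = ", ")))
  if (!is.null(x$label)) {
    cat(sprintf("  labels: high=%d, low=%d\n", sum(x$label == 1L), sum(x$label == 0L)))
  }
  invisible(x)
}

#' Names of the feature columns of a cohort
#' @param cohort A cohort table (or any data.frame with `feat_*` columns).
#' @return Character vector of feature column names, in order.
#' @export
feature_names <- function(cohort) {
  grep("^feat_", names(cohort), value = TRUE)
}

#' Feature block of a cohort as a numeric matrix
#' @inheritParams feature_names
#' @return Numeric matrix, one row per participant.
#' @export
cohort_features <- function(cohort) {
  as.matrix(cohort[, feature_names(cohort), drop = FALSE])
}

# logical vector: TRUE for privileged rows
is_privileged <- function(cohort) {
  cohort$group == attr(cohort, "privileged")
}

#' Label a cohort by median (or mean) split of the mental-health score
#'
#' Dichotomizes the continuous score into high (1) / low (0) at the sample
#' center. The tie rule is deterministic: scores strictly greater than the
#' center are labeled 1; the center itself is labeled 0. The center is the
#' median by default; the mean is exposed as an option because both
#' conventions are in use for this kind of survey score.
#'
#' @param cohort A cohort table with all scores present and finite.
#' @param center `"median"` (default) or `"mean"`.
#' @return The cohort with an integer `label` column added (or replaced).
#' @export
median_split_label <- function(cohort, center = c("median", "mean")) {
  center <- match.arg(center)
  bad <- is.na(cohort$score) | !is.finite(cohort$score)
  if (any(bad)) {
    stop_config(paste("scores missing or non-finite for ids:",
                      paste(cohort$id[bad], collapse = ", ")))
  }
  cutoff <- if (center == "median") stats::median(cohort$score) else mean(cohort$score)
  cohort$label <- as.integer(cohort$score > cutoff)
  cohort
}

#' Set feature cells missing completely at random
#'
#' Each feature cell is independently set to `NA` with probability `rate`,
#' to exercise median imputation downstream. Ids, groups, scores and labels
#' are never touched.
#'
#' @param cohort A cohort table.
#' @param rate Missingness probability in \[0, 1).
#' @param seed Integer seed; the mask is a pure function of it.
#' @return The cohort with missing feature cells.
#' @export
inject_missingness <- function(cohort, rate, seed) {
  if (!is.numeric(rate) || length(rate) != 1 || is.na(rate) || rate < 0 || rate >= 1) {
    stop_config("rate must be a single number in [0, 1)")
  }
  check_count(seed, "seed", min = -.Machine$integer.max)
  if (rate == 0) return(cohort)
  fcols <- feature_names(cohort)
  n <- nrow(cohort)
  withr::with_seed(as.integer(seed), {
    mask <- matrix(stats::runif(n * length(fcols)) < rate, nrow = n)
  })
  for (j in seq_along(fcols)) {
    cohort[[fcols[j]]][mask[, j]] <- NA_real_
  }
  cohort
}

#' Write / read a cohort as CSV with a JSON sidecar
#'
#' The CSV has columns `id,group,feat_1..feat_k,score[,label]`; missing cells
#' are empty. The sidecar (`<path>.json`) records the privileged group level
#' so the table round-trips losslessly.
#'
#' @param cohort A cohort table.
#' @param path CSV file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns a
#'   cohort table.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  sidecar <- list(privileged = attr(cohort, "privileged"),
                  group_levels = levels(cohort$group))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    x$group <- factor(x$group, levels = sidecar$group_levels)
    as_cohort(x, privileged = sidecar$privileged)
  } else {
    as_cohort(x, privileged = sort(unique(x$group))[1])
  }
}

# ---- shared error helpers -------------------------------------------------

stop_config <- function(message) {
  stop(errorCondition(message, class = c("fairaudit_config_error", "error", "condition")))
}

stop_undefined_metric <- function(message) {
  stop(errorCondition(message, class = c("fairaudit_undefined_metric", "error", "condition")))
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != round(x) || x < min) {
    stop_config(sprintf("%s must be a single integer >= %s", name, format(min)))
  }
  invisible(TRUE)
}
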