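---
title: "Auditing and repairing gender bias in small-cohort behavioral classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing and repairing gender bias in small-cohort behavioral classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fairaudit)
```

## The problem

Phone-sensed behavioral features — call volume, response rate, contact
diversity, tie strength, temporal rhythms — can classify whether a person's
self-reported mental-health score is high or low with usefully high
accuracy. But men and women use phones differently, so a classifier trained
on pooled data can key on gendered usage patterns rather than on health
signal, and perform very differently for the two groups. `fairaudit`
packages three things: a synthetic cohort generator that reproduces this
failure mode, a repeated cross-validated audit of five classifier families
against six group-fairness quantities, and a preprocessing-only mitigation
(a disparate impact remover) with a tunable repair amount.

This vignette records the modeling choices, their rationale, and what the
synthetic experiments do and do not demonstrate.

## The audit model

Predictions come from stratified k-fold cross-validation (default k = 5),
reshuffled over `n_iterations` (default 100) seeded repetitions. Folds are
stratified on the joint (label x group) cell: at a cohort size of ~55, plain
random folds frequently lack one group or one class entirely, which would
leave group metrics undefined in many iterations. Per-iteration metrics are
computed on predictions pooled across a full pass of folds — per-fold group
cells are far too small to carry rates of their own.

Everything fitted is fitted inside the training fold: imputation medians,
standardization moments, SMOTE resampling, PCA loadings, and (when enabled)
the repair's quantile maps. Held-out folds keep their original class ratio.
The leakage tests assert bit-identical fitted artifacts under arbitrary
mutation of held-out rows.

The preprocessing order is impute, standardize, SMOTE, then PCA fitted on
the balanced matrix, following the narrative order of the emulated
protocol; the order of SMOTE relative to scaling and PCA is genuinely
ambiguous in that protocol, so `preprocess_config(smote_first = FALSE)`
exposes the alternative. SMOTE uses the technique's canonical k = 5
neighbors, falling back to minority-size − 1 on very small folds. PCA keeps
5 components — on generated cohorts these carry more than 99% of feature
variance by construction — with a cumulative-variance fallback when the
training rank is lower.

Classifier families are delegated to standard implementations behind one
fit/predict contract: logistic regression (`stats::glm`), an RBF-kernel SVM
(`e1071::svm`), a random forest with 100 trees and depth capped at 6
(`ranger`), k-nearest neighbors (`class::knn`, k = 5), and a
single-hidden-layer perceptron (`nnet`, 8 units, entropy loss, iteration
cap raised to 1000 so it converges on 5-dimensional inputs). Only the
random-forest pair (trees, depth) is prescribed by the emulated protocol;
the rest are library defaults, recorded in the run manifest, because the
audit's subject is group disparity rather than tuning. The protected
attribute itself is never given to the classifier: excluding it isolates
the indirect pathway — group recoverable from behavioral features — that a
feature-level repair can actually address.

## The fairness metrics

All six quantities derive from group-conditioned confusion counts; every
metric is checked in the tests against a brute-force per-row recomputation
at tolerance 1e-12. Conventions worth stating:

* Differences are privileged minus unprivileged, so positive values mean
  the model favors men; `statistical_parity_difference(flip_sign = TRUE)`
  gives the opposite convention.
* Disparate impact is the unprivileged/privileged ratio of favorable
  prediction rates, flagged below the conventional 0.8 threshold.
* The balanced error rate is the *mean* of the two group error rates. One
  sometimes sees it printed with a minus sign, but its defining worked
  example — 90 privileged rows all right, 10 unprivileged rows all wrong,
  overall error 0.1, BER (0 + 1)/2 = 0.5 — and the literature it comes from
  use the mean, which is what the package computes.
* Undefined metrics (an empty group, a zero TPR/FPR denominator, a zero
  privileged positive rate) raise structured conditions rather than
  returning NaN, so the harness can count and report skipped iterations
  instead of silently averaging over garbage.

### Significance testing

The before/after comparison applies a two-tailed Welch t-test to the
per-iteration metric vectors, as the audit protocol prescribes. The
audit's *group accuracy* test, however, compares per-person mean
correctness between men and women (Welch, participants as sampling units)
rather than the per-iteration accuracy vectors. The reason is statistical:
iterations of cross-validation on one fixed cohort are not independent
replicates — per-iteration group accuracies are nearly constant across
reshuffles — and a t-test across iterations treats n_iterations as the
sample size, inflating the type-I error enormously (we measured 77%
rejection on null cohorts for that construction, against 5.5% for the
per-person construction over 500 replicate audits). The pooled-variance
variant is available via `t_test_two_tailed(var_equal = TRUE)`.

## The disparate impact remover

For each feature and group the repair stores the group's sorted training
values. The empirical CDF is F_g(x) = #(values ≤ x)/n_g; quantiles are
type-1 (left-continuous inverse) quantiles; the repair target at
probability p is the cross-group median of the group p-quantiles, which for
two groups is the midpoint of the two quantile curves — making the repair
symmetric in the groups. A value x in group g becomes

    (1 − λ) x + λ q̄(F_g(x))

Evaluation is exact at p = F_g(x) rather than interpolated on a fixed
probability grid: with type-1 (step) quantile functions, grid interpolation
between steps would bias small-sample repairs (on a 3-member group, the
1/3-quantile target would be off by a third of a step), whereas exact
evaluation reproduces hand-computable cases like the {1,2,3} vs {11,12,13}
toy, which full repair maps onto the common curve {6,7,8}. Out-of-range
values clamp to the [0, 1] probability range, i.e. to the group
minimum/maximum seen at fit time; rank order within each group is preserved
for every λ, strictly for λ < 1 (full repair may map distinct values to a
common target where a coarser group's quantile curve steps). The default is
full repair (λ = 1), the convention of reference implementations of this
mitigation family; `repair_lambda` in the harness accepts any amount.

Repair is applied to raw features before the preprocessing chain, matching
a mitigation defined as modifying "the data set" ahead of training, and is
fitted per training fold like every other transform.

## The synthetic cohort generator

The generator emulates a private mobile-sensing cohort: default 55
participants with an expected 38% women (the minority and unprivileged
group; men are the privileged level), ten phone-usage features, and an
MHI-like score (centered at 68, SD 12) that is median-split into high/low
labels (strictly-above-median is 1; the median itself is 0 — a fixed
convention because the split must be deterministic; a mean split is exposed
as an option since both conventions appear in survey practice).

Structure: a 5-dimensional latent Gaussian z drives everything. Features
are linear readouts z·L plus measurement noise (SD 0.05), with L drawn once
per seed and scaled to unit feature variance — so the feature block is
effectively rank 5 and the PCA step's ">99% variance in 5 components"
property holds by construction. The true health index is β'z plus score
noise (`noise_sd`, default 0.3 ≈ a reliability-0.9 measurement), minus a
legacy offset for women of 0.5·`legacy_strength` index-SD. Because the
index uses the *shared latent* and not the shifted observed features,
`legacy_strength = 0` makes labels independent of gender in expectation
regardless of any feature shift — the generator's no-bias null is exact.

The gender feature shift (`group_shift`, in feature-SD units of per-feature
RMS magnitude) is where the audit's phenomenology comes from, and its
composition is a deliberate design choice. A purely generic mean shift
turns out not to reproduce the phenomenon this literature reports: if
women's label deficit is real and the model can see gender, predicting
women lower is *correct*, and the group accuracy gap stays at the sampling
floor. What does reproduce it is a *confound*: 90% of the shift magnitude
runs along the score-readout direction (gendered phone use that mimics poor
mental health, making women look sicker than the legacy deficit warrants),
and the remainder along a direction orthogonal to the whole latent readout
span (pure "style", which the 5-component PCA bottleneck discards, so the
model cannot recover gender and compensate). Under this structure a
baseline classifier under-predicts women's favorable labels well beyond
their true deficit — large Δaccuracy, DI far below 0.8 — and full quantile
repair, which removes exactly the per-feature group shift, restores both
parity and women's accuracy. These constants (confound weight 0.9, legacy
scale 0.5, noise SD 0.3) were fixed by this reasoning and are not exposed
as knobs.

`inject_missingness` knocks out feature cells completely at random at a
configured rate, purely to exercise median imputation.

### What the synthetic experiments show — and don't

On generated cohorts (n = 200, shift 0.6, legacy 0.7, logistic-regression
audits, 10 iterations each, 20 seeds) the test suite verifies the full
before/after story: mean DI below 0.8 at baseline, in [0.8, 1.25] after
full repair, the mean absolute accuracy gap at least halved, and overall
accuracy within 5 points of baseline. On null cohorts (500 replicates) the
group t-test rejects at 5% ± 2%. Those problem sizes (10 iterations rather
than 100, n = 200 rather than larger) are the package's chosen
simulation scale; all of these behaviors are stable well below the
defaults.

What passing these tests does *not* show: that real phone-sensing cohorts
have this generative structure. The generator's confound is linear and
Gaussian; real gendered usage differences may be nonlinear, heteroscedastic
or label-dependent, in which ways the quantile repair (which equalizes
marginals but cannot remove noise, multivariate structure, or a truth-level
group dependence) may help less — or differently. The generator also models
binary gender only, inheriting that limitation from the setting it
emulates. Results on synthetic cohorts validate the *machinery*, not any
claim about a particular real dataset.

## Numerical and degenerate-input choices

* Zero-variance features standardize with scale 1 and a warning.
* All-missing features, single-class training data, singleton groups, and
  unseen group levels are structured errors naming the offender.
* An iteration whose training fold loses a class, or whose pooled metrics
  are undefined, is recorded as skipped with its reason; an audit aborts if
  more than half its iterations skip.
* Every stochastic step (generation, missingness, shuffling, SMOTE, model
  seeds, knn tie-breaks) is seeded; an entire audit is a pure function of
  (cohort, config), and the tests assert bit-level reproducibility.
* Repair models serialize quantile values as `%.17g` strings because the
  empirical CDF is discontinuous at the stored points: a round-trip that
  loses one ulp can shift a rank.

## Known limitations

* Only one binary protected attribute; no multi-attribute or intersectional
  audits.
* Only preprocessing-stage mitigation; in-processing and post-processing
  families are out of scope.
* No hyperparameter search; classifier defaults are frozen for
  reproducibility, not optimality.
* The per-iteration SDs reported in tables inherit the repeated-CV
  dependence discussed above: they describe resampling variability on one
  cohort, not sampling variability across cohorts.
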