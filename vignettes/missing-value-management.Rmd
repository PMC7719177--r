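---
title: "Managing missing values in ordinal behavioral rating scoresheets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Managing missing values in ordinal behavioral rating scoresheets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Minimal-feature autism classifiers -- a 9-feature logistic regression
(LR9) trained on ADOS Module 2 scoresheets and a 7-feature alternating
decision tree (ADTree7) trained on ADI-R 2003 scoresheets -- can be run
on ratings that non-experts produce from short videos of children. Each
video is scored by several raters on a 30-item ordinal questionnaire
(items run from 0, typical behavior, to 3 or 4, severely atypical).
Variable video length and quality mean raters often cannot answer every
item, and a missing model feature breaks or degrades the classifier.

`featrepl` implements, behind a single `rating_table` exchange object,
the whole missing-value tool chain for this setting:

* **listwise deletion** (the baseline): a training record is dropped if
  any model feature is missing; a test *rating* is dropped likewise, and
  a subject becomes unpredictable when all of its ratings are dropped;
* **univariate imputation**: mean / median / mode of the observed
  training values of the same feature;
* **iterative multivariate imputation**: round-robin prediction of each
  model feature from the other model features (ridge, regression-tree or
  two-component Gaussian-mixture estimators);
* **general feature replacement**: a missing model feature is filled
  with the record's own value of its closest substitute from the full
  30-item questionnaire, closeness scored once on the training table by
  Spearman correlation, Euclidean proximity, or mutual information;
* **dynamic feature replacement**: the same substitution with the map
  re-estimated, per record, on the training records most similar to it.

Replacement *substitutes* a question rather than adding one: the number
of filled entries always equals the number of missing model features,
and the ranked map (`as.data.frame(build_general_map(...))`) doubles as
an audit trail of which questions can stand in for which.

## Evaluation design

`run_pipeline()` reproduces the study design the methods were built
for. Per repeat `r` (seed `base_seed + r - 1`):

1. the missing-value method is fitted on the training table;
2. classifier hyperparameters are grid-searched by stratified 10-fold
   cross validation scored by UAR (unweighted average recall, the mean
   of sensitivity and specificity), the missing-value method refitted
   inside each fold's training split so nothing leaks from the held-out
   fold;
3. the best model is refitted on the full training table;
4. test ratings are completed per rating (dynamic methods build a
   per-record map), each subject's raters are aggregated by mode (ties
   toward the smallest value; missing only if all raters are missing),
   residual gaps are filled by the univariate mode fallback, and the
   consensus vector is scored once per subject;
5. sensitivity, specificity, UAR, AUC-ROC and AUC-PR are recorded.

The baseline instead drops every rating containing a missing model
feature and excludes subjects with no surviving rating from the metric
denominators, reporting their count -- they are not counted as errors.
`compare_methods()` runs all 13 methods and tests each method-by-metric
mean against the baseline with a two-sided Welch t-test; Bonferroni
flags use the whole report (non-baseline methods x 5 metrics) as the
family. `missingness_analysis()` compares per-subject missing counts
between groups (diagnosis, gender, age group) per feature plus one
overall test, with the family sized accordingly.

```{r}
library(featrepl)
tb <- simulate_rating_study(seed = 1)
cfg <- pipeline_config(model = "adtree", imputation_method = "repl_nn",
                       n_repeats = 5, adtree_grid = c(5L, 10L))
run_pipeline(tb$train, tb$test, cfg)
```

## The synthetic cohort generator

The real training archives and video ratings are not redistributable,
so the package carries a generator that emulates their statistical
shape. Each subject has a latent severity `z ~ N(effect * 1[ASD], 1)`;
feature `f` with loading `l_f` observes `l_f z + sqrt(1 - l_f^2) e` and
is discretized at fixed quantile cut-points of the class-mixture
marginal, so every ordinal level is used at roughly equal rates (this
keeps mode and median imputation non-degenerate). Raters perturb each
value by one step with probability `rater_noise`, clipped to the
domain -- the simplest exchangeable-rater noise consistent with an
ordinal scale. Missingness mechanisms knock entries out with
probability `clip(rate * (1 + slope * d), 0, 1)` where `d` is 0 (MCAR),
a scaled observed driver column (MAR), the entry's own scaled value
(MNAR on the value), or the class indicator (MNAR on the label, the
mechanism actually observed in video ratings: items tied to speech and
play are blank more often for ASD children).

`simulate_rating_study()` freezes the study conditions: 2000
single-rater training records; a test set of 140 subjects x 3 raters x
30 features, class-balanced and balanced for age and gender; training
missingness MCAR with per-feature rates cycling 0.02-0.18 (0.30 for
`pretend_play`); test missingness label-driven for five speech- and
play-related items (`pretend_play` at base 0.33, slope 0.5, realized
around 0.41) over an MCAR background cycling 0.02-0.12. Defaults were
chosen once for realism: class separation `effect = 2.5` SD (these
instruments separate the classes strongly), loadings cycling 0.55-0.85
(inter-item correlations of roughly 0.3-0.7), `rater_noise = 0.25` for
untrained raters.

What the generator does *not* emulate: multi-dimensional symptom
structure (one latent factor only), rater-specific bias or skill,
item-specific response styles, and any dependence of missingness on
severity *within* a class. Passing tests therefore show that the
methods behave as designed under a faithful one-factor rendition of the
study -- not that the published performance numbers re-appear, which
would require the original archives.

## Numerical choices

* **Replacement scores** are computed on pairwise-complete records with
  a minimum overlap of 30 (Spearman and plugin MI are unstable below);
  candidates that miss the overlap, or whose score is undefined (e.g.
  Spearman against a constant column), are skipped. The Euclidean score
  is the negative *root-mean-square* difference: a raw Euclidean sum
  grows with the overlap size and would favour candidates with more
  missingness; RMS scaling makes candidates with different overlaps
  comparable while an exact copy still scores 0.
* **Mutual information** uses the plugin (maximum-likelihood) estimator
  on the joint count table, in nats, with no bias correction --
  adequate for 4-5 letter ordinal alphabets at these sample sizes.
* **Dynamic similarity** is Euclidean over the features observed in the
  test record (averaged over those also observed in each training row),
  with `k = max(50, 5%)` of the training records by default; the
  selected rows keep their original order so that `k = n` is
  bit-identical to the general map. Training-side completion for the
  dynamic methods uses the general map -- the per-record map is a
  test-time device.
* **Iterative imputation** initializes with medians, visits features in
  ascending missingness, refits each conditional on the records where
  the target was observed, and stops when the largest change falls
  below `1e-3` or after 10 sweeps. The ridge conditional uses the
  closed form with penalty 1; the tree conditional is depth-capped at
  5; the Gaussian mixture has 2 components (EM tolerance `1e-4`, at
  most 200 steps) and imputes with the mixture conditional mean.
  Imputer hyperparameters are deliberately *not* part of the grid
  search. Imputed values are carried as reals; `round_imputed` snaps
  them back to the ordinal grid if required.
* **Classifiers**: the logistic model maximises the penalised
  likelihood with `||w||^2 / (2C)` by Newton iterations (gradient
  tolerance `1e-6`); `C` is grid-searched over `{0.01, 0.1, 1}` with
  the lower bound enforced as a guard against degenerate
  regularization. The alternating decision tree follows the standard
  boosting induction (root `0.5 ln(W+/W-)`, precondition-gated rules
  minimising `Z`, score smoothing +1), with rounds grid-searched over
  `{3, 5, 7, 10}` and greedy ties broken by (precondition, feature,
  threshold) order for determinism.
* **Degenerate Welch samples** follow a convention: both samples
  constant and equal gives `p = 1`, constant and unequal gives `p = 0`.
* **Mode ties** break toward the smallest value everywhere (fills,
  aggregation), which keeps every step deterministic.

## Design decisions on open points

The source design leaves several details open; the package decides them
as follows. Free-response and age-of-onset interview items are out of
scope: only ordinal items are supported. Other model features *are*
allowed as replacement candidates (an exclusion flag exists). General
maps are computed on pairwise-complete pairs of the raw training table
rather than after a preliminary imputation. Repeats re-seed both the
fold draw and the grid search. Baseline metrics use the per-subject
consensus of the surviving ratings. Imputation runs per rating before
mode aggregation (the alternative is exposed as
`impute_after_aggregation`).

## Problem sizes

The test suite and the acceptance script run entirely on generated
data. The heavier checks use the frozen study conditions above (140
test subjects, 2000 training records) across 20 seeds with a fixed
6-round tree and a single repeat per seed; the acceptance script runs
the full 5-repeat, 10-fold grid-searched design for a handful of
methods at one seed. Property-style suites (oracle equivalences,
round-trips, argmax checks) use tables of 10-120 records, which is
enough to pin the arithmetic without inflating runtimes.

## Known limitations

* A single latent factor generates the features, so the generator
  cannot distinguish replacement scores that would differ under
  multi-factor structure; on this data correlation, proximity and MI
  rankings largely agree.
* With one repeat and a single grid point the pipeline is fully
  deterministic, so per-repeat SDs collapse to zero; Welch comparisons
  need either the multi-point grid (fold randomness) or multiple seeds.
* The Gaussian-mixture conditional falls back to the ridge closed form
  when EM cannot fit (singular within-component covariance on small
  strata).
* Plugin MI is biased upward at small overlaps; the overlap floor
  mitigates but does not remove this.
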