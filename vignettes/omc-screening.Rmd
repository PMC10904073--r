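---
title: "Merged cross-validation and OMC feature selection for drug-response screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merged cross-validation and OMC feature selection for drug-response screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omcscreen)
```

## The estimation problem

`omcscreen` targets the common pharmaco-omics situation: a cohort of a few
dozen drug-treated cancer patients, each with a binarized best response
(responder = complete or partial response; nonresponder = stable or
progressive disease) and one or more tumor molecular profiles whose feature
counts dwarf the sample count. The scientific questions are (i) which
profile × algorithm combinations are predictive at all, (ii) which small
feature subsets carry the signal, and (iii) whether predicted response
groups also separate survival.

## Merged cross-validation

All model evaluation uses stratified K-fold CV in which the K out-of-sample
prediction blocks are **merged** before any metric is computed: per
repetition there are exactly n out-of-sample predictions, one per sample,
and one confusion matrix, one MCC and one ROC-AUC are computed from them.
We never average per-fold metrics — with n = 70 and K = 10 a fold-wise test
set has 7 samples, fold-wise MCCs are dominated by noise, and averages would
not be comparable across K (5, 10 and n are all supported; K = n is
leave-one-out, where stratification is vacuous).

Probability-type classifiers are thresholded at 0.5 (strictly above =
responder); margin-type classifiers (the two SVCs) are thresholded at 0 and
contribute their signed decision value to ROC-AUC, which is rank-invariant,
so no probability calibration is needed. The MCC of a confusion matrix with
a zero marginal — a model predicting one class for everyone — is **undefined**
and is carried as a typed `NA` sentinel, never as 0: an undefined cell means
"this model never committed to both classes", which is categorically
different from "random-level performance". Repetition summaries take the
median over the defined repetitions and count the undefined ones; a cell
whose five repetitions are all undefined stays blank in tables and heatmaps.

Each CV repetition is driven by one integer seed that determines both the
fold assignment and every stochastic learner inside that repetition, so a
repetition is a single reproducible unit; one seed list (default `0:4`) is
shared by every cell of an evaluation grid so cells are comparable.

## OMC: optimal model complexity

For p ≫ n, each outer-training set goes through nested selection:

1. rank all features by the two-group ANOVA F test (for two groups,
   F = t² of the pooled-variance t statistic — the test suite uses this
   identity as an oracle); constant features get p = 1 and rank last, and
   p-value ties break lexicographically by feature ID so rankings are
   deterministic;
2. for each candidate k in `seq(2, floor(n_train/2), by = k_step)`, evaluate
   the classifier restricted to the top-k features by inner merged CV
   (default stratified 10-fold, mirroring the outer protocol), **recomputing
   the ranking inside every inner training split** — the stricter, fully
   nested reading that keeps selection bias out of the inner estimate;
3. pick the k with the highest inner MCC, ties to the smallest k
   (parsimony); if every k is undefined, fall back to the smallest k with a
   warning;
4. refit on the outer-training set restricted to the top-k of its own
   ranking; the resulting predictor touches held-out samples only through
   those k features.

Two readings of the "top 2 to n/2" grid are possible: n as the full cohort
or n as the outer-training count. They differ by at most one fold's worth of
features; we implement the per-fold reading (`k ≤ floor(n_train/2)`) because
it keeps the grid well-defined for any split, and expose
`omc_control(k_max =)` for the fixed-cap reading. `k_step` coarsens the grid
for speed; the default is 1.

Selection stability is summarized by `feature_selection_frequency()`, the
count of how often each feature was selected across outer folds and
repetitions — the basis for nominating a consensus signature.

## The classifier registry

Eight algorithms behind one fit/score/classify contract, with library-default
hyperparameters recorded verbatim in the run manifest rather than tuned:

| id | backend | score |
|---|---|---|
| `cart` | `rpart` (cp 0.01, minsplit 20) | class probability |
| `rf` | `ranger`, 100 trees, probability forest | class probability |
| `xgboost` | `xgboost`, 100 rounds, eta 0.3, depth 6 | class probability |
| `lgbm` | leaf-wise histogram boosting via xgboost (`grow_policy = "lossguide"`, 31 leaves, eta 0.1) | class probability |
| `logistic` | ridge-penalized logistic regression, `glmnet(alpha = 0, lambda = 1/n)` | class probability |
| `svc_linear`, `svc_rbf` | `e1071::svm`, cost 1 (gamma 1/p for RBF) | signed margin |
| `knn` | `class::knn`, k = 5 | neighbor vote fraction |

Two backends deserve a note. The `lgbm` slot is leaf-wise, histogram-binned
gradient boosting — the algorithm LightGBM popularized — realized through
xgboost's `lossguide` grow policy with LightGBM's default leaf budget.
`logistic` is ridge-penalized because the screening design requires the
all-features mode to run at p ≫ n, where unpenalized maximum likelihood
does not exist; `lambda = 1/n` matches the weakly-regularized default
(C = 1) customary in scikit-learn-style pipelines.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
tested: 70 samples with a 41/29 nonresponder/responder split, 1,000 features
of which 5 are informative at a standardized latent shift Δ = 1.5, five CV
repetition seeds. Informative features are planted on a latent Gaussian
scale and mapped to each profile kind's range — `exp` for FPKM kinds, a
logistic squash into (0, 1) for methylation betas, identity for log2-RPM,
an additive shift around the neutral copy number 2 for CNV — so one
effect-size parameter means the same thing across kinds. Planted features
sit in the first columns with an `info_` ID prefix, so recovery metrics need
no side table. The copy-number generator emits per-sample segment tables
plus a gene map and retains exact per-gene ground truth computed by direct
interval arithmetic, giving the overlap-based aggregation an independent
oracle.

Survival: overall survival is exponential with a nonresponder median of 20
months and a responder hazard ratio of 0.4 (echoing the order-of-magnitude
gap reported between responder and nonresponder medians in gemcitabine
cohorts); progression-free survival is OS × Uniform(0.3, 1), which
guarantees PFS ≤ OS; censoring truncates follow-up at a uniform fraction of
the true OS time for a default 20% of patients, and a follow-up cut before
progression censors PFS too. At `effect_size = 0` and `hr_responder = 1`
every downstream signal statistic is null-calibrated, which the tests check
empirically (Welch p-values and log-rank p-values uniform, permutation null
centered at 0).

What the generator does **not** emulate: the empirical correlation structure
of real tumor profiles (an optional block-equicorrelation knob exists,
default off), batch effects, missingness mechanisms beyond
missing-completely-at-random, or non-exponential hazards. Passing tests
therefore demonstrate that the machinery is correct and that the procedure
recovers planted signal under idealized conditions — not that any particular
real-data performance number will reproduce.

## Survival comparison of predicted groups

`compare_predicted_groups()` joins one repetition's merged out-of-sample
classes (default: the first configured seed; a majority vote across
repetitions is available and the choice is recorded in the output) to the
cohort's OS/PFS records and reports, for the four groups — actual and
predicted responders and nonresponders — the group sizes, Kaplan–Meier
medians (smallest time at which the product-limit curve reaches 0.5 or
below; undefined if it never does), and four pairwise log-rank tests:
actual-R vs actual-NR, predicted-R vs predicted-NR, actual-R vs predicted-R,
actual-NR vs predicted-NR. Cox models use Breslow handling of ties (the
common default; the choice only matters with heavily tied times) and
standardize continuous covariates to per-SD hazard ratios so jointly modeled
features are comparable; binary covariates are left on their natural scale.
Rank-deficient multivariate designs abort with a diagnostic naming the
aliased covariates. Welch t-tests for differential features report raw
p-values by default; Benjamini–Hochberg correction is a call away via
`p.adjust` but is deliberately not applied silently.

## Numerical choices and degenerate inputs

- Undefined MCC, single-class ROC-AUC, and a Kaplan–Meier curve that never
  reaches 0.5 all return `NA`, never a substitute value.
- The stratified fold allocator gives each class fold counts differing by at
  most one and places remainders on the currently smallest folds, so total
  fold sizes are also balanced; which folds take remainders is randomized by
  the repetition seed.
- Sub-seeds for folds and learners are derived by a fixed integer recurrence
  kept below 2³¹, so any small user seed yields valid R seeds and
  bit-identical reruns.
- ANOVA ranking treats within- and between-group sums of squares below
  machine tolerance as exact zeros (constant feature → p = 1, rank last;
  zero within-variance separator → p = 0, rank first).
- The empirical permutation p-value uses the +1 correction,
  (1 + #{null ≥ observed}) / (1 + n_perm), and can never be 0; the full
  pipeline, including OMC selection, reruns inside every permutation so
  selection bias is part of the null (the default is 50 permutations,
  configurable).
- glmnet requires ≥ 2 columns; single-feature fits are padded with one
  all-zero column, which leaves the fit unchanged.

## Problem sizes used by the test suite

The acceptance-style tests run the full study conditions (n = 70, p = 1,000,
5 planted features, five repetitions) for RF-OMC with 10-fold outer and
inner CV; the permutation calibration uses 50 permutations of the
ridge-logistic OMC model with a coarsened grid (inner 5-fold, k step 5), and
the training-size comparison (5-fold vs leave-one-out) uses RF-OMC with the
same coarsened grid. Unit tests use smaller cohorts (n = 20–40, p ≤ 200) so
the default suite completes in minutes on one CPU.

## Known limitations

- **LOOCV and threshold-based classifiers under class imbalance.** With
  leave-one-out, the held-out sample's class is always underrepresented in
  training; for models whose hard class comes from thresholding a calibrated
  probability (ridge logistic especially) this biases predictions against
  the held-out class and can make merged LOOCV MCC *lower* than 5-fold MCC
  even on strong signal. Tree ensembles are much less sensitive, and the
  monotone improvement with training size shows cleanly for RF-OMC.
- The single-seed choice feeding the predicted-group survival comparison is
  arbitrary by construction; use `repetition = "majority"` when a
  consensus view matters.
- Sequential execution only; grid cells are contractually independent
  (identical results in any order), but scheduling them in parallel is left
  to the caller.
- The package evaluates screening performance; it does not produce a
  deployable calibrated classifier, and nothing here replaces prospective
  validation of a nominated signature.
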