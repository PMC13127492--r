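---
title: "Methods: lagged discovery and double machine learning for initiation outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lagged discovery and double machine learning for initiation outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lagdml)
```

## The problem

Large longitudinal cohorts follow thousands of adolescents across repeated
assessment waves and record hundreds of correlated time-varying measures —
behavioral traits, family environment, sleep, screen time, genetic risk
summaries — alongside rare, absorbing initiation outcomes such as first use
of alcohol, nicotine or cannabis. Two questions arise. First, *which* past
measures carry robust predictive signal for near-term initiation? Second,
*how large* is the adjusted association of each such measure once all other
past measures are controlled?

`lagdml` answers both with a two-stage pipeline on discrete-time panel
data: one row per subject and follow-up interval ("step"), an interval-level
binary outcome `y` (1 = initiated in this interval), and a per-outcome
at-risk indicator `m` that drops to 0 permanently after first use, so
post-initiation rows never enter any analysis.

## Temporal ordering and feature construction

All model inputs are lagged: for each raw predictor `p` and lag `k`,
`p_Lk` holds the subject's own value `k` intervals earlier, and is missing
when no such interval exists. Lags are computed from the (subject, step)
key, never from row order, and never cross subjects. Optional change scores
`p_D1 = p_L1 - p_L2` capture recent dynamics while remaining entirely in
the past. Raw (contemporaneous) predictor columns are excluded from every
model, so predictors always temporally precede outcomes — the Granger
logic under which a directional edge means "past values of `p` improve
prediction of future initiation".

The default lag order is 2. Change scores are off by default in discovery
and available behind `deltas = TRUE`; the directional screening is defined
on the `_Lk` columns and the delta variant is exposed for sensitivity
analyses.

Estimation rows for an outcome are those with `m = 1` and `step >= 1`
(at risk, with at least one prior interval). An outcome enters the analysis
only if it has at least 500 eligible rows, event prevalence inside
(0.005, 0.995), and non-constant outcome values. The bounds are deliberately
permissive — their job is to exclude quasi-constant outcomes, not to select
cohorts — and are configurable.

Preprocessing is intentionally simple: numeric coercion (uncoercible
entries become missing), non-finite values treated as missing, per-column
median imputation with a fallback of 0 when a column has no observed value,
then z-scoring. Constant columns become all-zero. The fitted medians, means
and SDs are stored so the identical transform replays on held-out rows.
Median imputation is defensible only under simple missingness, which is
exactly what the synthetic generator produces (see below); with informative
missingness a model-based imputation would be needed and is out of scope.

## Stage 1: discovery by stability selection

For each eligible outcome we fit an elastic-net logistic regression of the
interval outcome on all lagged features. Defaults and their reasons:

* **Mixing `l1_ratio = 0.5`** — equal L1/L2 mixing keeps sparsity while
  letting groups of correlated predictors share weight rather than
  arbitrarily picking one.
* **Balanced class weights** — initiation events are rare (a few percent
  per interval); weighting classes inversely to frequency stops the
  penalized fit from shrinking everything to the majority class.
* **Penalty strength** — chosen once on the full eligible data by
  cross-validated deviance with folds that partition *subjects* (repeated
  measures never straddle folds), taking the sparser one-standard-error
  penalty, then held fixed across all bootstrap replicates. Tuning inside
  each replicate would confound selection stability with tuning noise.
* **`n_bootstrap = 100`** — resolves stability scores to 0.01 at desk
  scale.
* **`nonzero_tol = 1e-8`** — on standardized coefficients, below any
  scientifically meaningful effect, above solver round-off.

Each bootstrap replicate resamples *subjects* with replacement; a subject
drawn twice contributes all its rows twice. Preprocessing statistics are
recomputed on each replicate's rows so no statistic ever pools information
across replicates. A replicate whose resampled outcome has fewer than two
rows in either class cannot be fit and is redrawn (default cap 10; beyond
that the outcome is too rare for stability selection and the run errors
rather than silently biasing the selection denominator).

The stability of a (lagged predictor, outcome) edge is the proportion of
replicates in which its coefficient exceeded the tolerance. Candidates are
ranked by stability, ties broken by absolute mean selected coefficient and
then name, so output order is fully deterministic.

## Stage 2: effect estimation by partialling-out

Edges at or above the stability threshold (default 0.6, inclusive; at most
25 per outcome) are re-estimated on a subject-level estimation split
(default 20% of subjects held out untouched). For an edge with treatment
`D` (the lagged predictor, standardized on the estimation rows so effects
read per 1 SD) and covariates `X` (all lagged variables up to the same lag
order, excluding the treatment column):

1. Subjects are partitioned into `n_folds = 5` cross-fitting folds.
2. Per fold, nuisance models `m(X) = E[Y|X]` and `g(X) = E[D|X]` are fit on
   out-of-fold rows — regression-mode random forests by default, for both
   the binary outcome and the continuous treatment — and predicted in-fold,
   giving residuals `Y - m(X)` and `D - g(X)`. No row is ever predicted by
   a model trained on any row of its own subject; the code asserts this on
   every run.
3. The adjusted effect is the no-intercept slope
   `theta = sum(Dres * Yres) / sum(Dres^2)` — the partialling-out form.
   Cross-fitted residuals are approximately centered by construction, so
   the intercept is off by default and available via
   `include_intercept = TRUE`.
4. The variance is a cluster-robust sandwich over subjects with the common
   small-sample factor `G/(G-1)`; confidence intervals use normal
   quantiles, appropriate for the thousands of clusters in the target
   regime (both documented in the output, both configurable).

`theta` is on the probability scale: the change in per-interval initiation
probability per 1 SD of the lagged predictor, adjusted for all other
lagged covariates.

Two genuinely open choices and how they were made:

* **Other lags of the treatment variable** stay in the covariate set by
  default (only the treatment column itself is excluded): the treatment is
  one lagged variable, and its other lags are legitimate confounders of
  the lag-specific effect. `exclude_treatment_lags = TRUE` gives the
  stricter variant.
* **Nuisance learner** defaults to 500 trees, minimum node size 5. The
  validation suite uses smaller forests (50–100 trees, node size 25);
  forest size barely moves the point estimates here because the nuisance
  signals are smooth, and the suite documents the sizes it uses.

## The synthetic generator and what it does (not) emulate

Because the motivating cohort data are access-controlled, the package
ships a generator that reproduces the *statistical structure* the pipeline
assumes, with known ground truth:

* predictors are stationary Gaussian AR(1) in time (default
  autocorrelation 0.5) and block-equicorrelated cross-sectionally (blocks
  of 10, within-block correlation 0.3), mimicking banks of correlated
  scale items;
* one standard-Gaussian latent confounder per subject, constant in time,
  loads on a configurable predictor subset (variance kept at 1) and enters
  the hazard logit additively — the simplest structure exhibiting
  confounding that must be removed through measured lagged proxies;
* initiation follows a discrete-time logistic hazard in the *previous*
  interval's predictor values (true edges are lag-1; a switch adds lag-2
  effects for stress tests), with absorbing at-risk bookkeeping; no event
  can occur in the first interval, which has no lagged history;
* missingness is completely at random (default 2%), matching what median
  imputation assumes;
* defaults emulate cohort scale: 10,000 subjects, 5 intervals, 200
  predictors, 5 causal effects of magnitude 0.5–0.8 on the logit scale,
  per-interval event probability around 5% giving cumulative initiation in
  the tens of percent.

It does **not** emulate informative dropout, measurement models, survey
weights, site structure, or calendar-time alignment — so passing tests
demonstrate correctness of the machinery under the stated assumptions, not
robustness to their violation on real cohort data.

### The ground-truth oracle

`true_effect_oracle()` computes the estimand by brute force: it simulates a
large panel from the generating mechanism and averages
`plogis(eta + beta) - plogis(eta)` — the change in hazard under a +1 SD
intervention on the lagged predictor, holding the confounder and all other
predictors at their generated values — over the *at-risk* rows. Averaging
over the at-risk population matters: initiation is absorbing, so high-risk
subjects leave the risk set early and the population the estimator sees is
survivor-selected; an oracle averaged over an unselected population would
target a different estimand.

## Validation scenarios

The end-to-end checks run scenarios chosen to isolate one property each
(2,000 subjects, 5 intervals; forests reduced to 50 trees, node size 25):

* **Debiasing** — one causal predictor (logit coefficient 0.3), a strong
  latent confounder (hazard coefficient 1.2) loading 0.5 on *all* ten
  predictors. Loading broadly makes the naive association unambiguously
  biased upward while giving the nuisance models enough measured proxies
  to remove the confounding — the regime where the method's "adequate
  control through lagged covariates" assumption holds. DML must land
  closer to the oracle than the naive slope in at least 90% of 100
  replicates.
* **Coverage** — coefficient 0.15, per-interval events ~4%, no latent
  confounder: an effectively linear hazard, where the +1 SD oracle and the
  projection slope the estimator targets coincide, so the check isolates
  the cluster-robust interval machinery. Empirical 95% coverage must fall
  in [0.90, 0.99] over 200 replicates. With larger coefficients the
  logistic curvature opens a gap between the discrete-shift oracle and the
  projection slope (about 17% relative at coefficient 0.3) and coverage of
  the discrete-shift estimand degrades — a property of the estimand pair,
  not an estimator defect.
* **Edge recovery** — 5 true lag-1 effects (|coefficient| 0.5–0.8) among
  100 predictors, 50 bootstraps, no latent confounder (a hazard-level
  confounder would make its proxy predictors genuinely predictive, so
  calling them "null" would be wrong). Every true edge must reach
  stability 0.8 and exceed the 90th percentile of null-edge stabilities
  across 10 seeds.
* **Exact identities** — the partialling-out slope against a normal-
  equations solve (1e-10), the sandwich variance against an explicit
  sum-over-clusters (1e-10) and its reduction to the HC estimator with
  singleton clusters, leakage truncation tests, and cross-fitting hygiene.

These problem sizes keep the full suite at desk scale while leaving every
comparison well-powered.

## Numerical and degenerate-input choices

* The elastic-net solve appends a short decreasing penalty path above the
  target penalty (warm starts) and tightens the convergence threshold to
  1e-9, so single-penalty fits are well converged and deterministic.
* A constant treatment, a constant outcome, a single cluster, and a fold
  with zero rows are hard errors with named messages, not silent results.
* Constant feature columns standardize to all-zero rather than dividing by
  a zero SD; all-missing columns impute to 0.
* Ranking ties break by |mean coefficient| then lexicographic name;
  stability scores are invariant to predictor column order.
* All randomness (generation, penalty folds, bootstrap draws, cross-fit
  folds, forests) derives from explicit seeds in the configuration
  objects; identical configuration and seed reproduce result tables
  byte-identically.

## Known limitations

* Causal interpretation requires the usual assumptions — correct temporal
  ordering, no unmeasured confounding beyond what the lagged covariates
  proxy, and correctly specified at-risk structure. The generator can
  violate the proxy assumption (set loadings to zero while keeping the
  hazard coefficient) and the estimator will then be biased, as it should
  be.
* The probability-scale effect is a projection-slope estimand; for large
  logit coefficients it differs from the discrete +1 SD effect by the
  logistic curvature.
* Stability selection here provides a ranking with an interpretable score,
  not a formal error-control bound.
* No multiplicity correction is applied across edges; downstream users
  comparing many edges should account for that.
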