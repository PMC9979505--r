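---
title: "Methods: robust counterfactual prediction and prescription of antihypertensives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: robust counterfactual prediction and prescription of antihypertensives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpmenu)
```

## The problem

Antihypertensive therapy is chosen from several drug classes whose effect on
systolic blood pressure (SBP) varies with patient characteristics —
comorbidity, demographics, labs. Observational EHR data record only the
outcome of the prescription actually given; choosing a better prescription
requires predicting the *counterfactual* next-period SBP under every option.
`bpmenu` implements an interpretable estimator for this task and an
evaluation harness that can score it against known ground truth on synthetic
cohorts.

## Visit construction

Raw inputs are three event tables: measurements (patient, day, kind, value),
prescription intervals, and static demographics. A patient enters the cohort
with evidence of hypertension (diagnosis, problem-list flag, any SBP > 130
or DBP > 90 mmHg), at least two SBP measurements within 180 days, and at
least one prescription among the seven menu classes.

Each patient's record is then cut into 90-day review periods anchored at the
first SBP measurement. Bins are half-open `[start, start + 90)` so every
measurement lands in exactly one period; a measurement precisely on a
boundary opens the next period. Time-varying features are averaged within
the period; periods without a value carry the last observation forward
(LOCF), a conventional choice for sparse EHR vitals, with the remainder
imputed by training-set medians. The outcome of a visit is the mean SBP
measured 90–180 days after the period start, i.e. during the next period.
The window offset is a parameter (`attach_outcomes(offset =)`) because "the
next visit" can also be read as starting from the period *end*; the default
uses the period-start reading, and the alternative is one argument away.
Visits without any SBP measurement in the outcome window have no usable
outcome and are excluded from model fitting (`modeling_visits()`).

Splits are by patient, never by visit (`split_by_patient()`, 80/10/10), so
no individual contributes to both training and evaluation.
Feature standardization (z-scores for numeric features, 0/1 for binary) is
fitted on training visits only and applied frozen to validation/test data.

## Outcome regressions

One regression per drug class is fitted on the training visits whose regimen
contains that class; combination-therapy visits therefore contribute to every
constituent class's sub-model. Four algorithms are available:

* **DRLR** (the package's own solver): absolute-loss regression hedged over
  a Wasserstein ball, in its regularized form
  `mean(|y - b0 - Xb|) + eps * ||(-b, 1)||_dual`. The ground metric is ℓ₂ by
  default (self-dual penalty `sqrt(1 + ||b||²)`), with ℓ₁ and ℓ∞ variants
  available. The intercept is left unpenalized — it is constant across
  patients and is excluded from the similarity metric anyway.
* **OLS** via the QR normal equations, with a 1e-8 ridge fallback for
  rank-deficient designs.
* **Lasso** via glmnet, parameterized so the objective is
  `mean squared error + lambda * ||b||_1` (glmnet's penalty is `lambda/2`
  under its loss scaling); a single-predictor design is solved by the exact
  soft-threshold formula.
* **CART** via rpart (variance-reduction splitting, depth-limited). A tree
  has no coefficient vector, so the "coefficients" slot holds per-feature
  total deviance reduction over primary splits — a non-negative surrogate
  importance. CART predicts directly through its leaves; using its
  importances as metric weights is possible but secondary.

### Solving the robust regression

The DRLR objective is convex but nonsmooth. The solver minimizes a smoothed
surrogate, `sqrt(r² + mu²)` in place of `|r|`, with BFGS and a continuation
schedule driving `mu` from the outcome's scale down to 1e-8, warm-starting
each stage. At `eps = 0` the problem is least absolute deviations, whose
optimum interpolates at least p+1 observations; a final polish enumerates
interpolating subsets among the smallest-residual points and keeps the best,
which recovers the exact optimum. The test suite verifies agreement with an
independent linear-programming oracle to within 1e-6 relative objective
(observed: machine precision).

Hyperparameters (`eps`, `lambda`) default to small fixed values (0.01, 0.1)
and can be selected on a validation set by grid search — validation MAE for
DRLR, MSE for the others.

## Counterfactual nearest-neighbor prediction

Similarity between two standardized visits is
`||x - z||_beta = sqrt(sum((x - z)² * beta²))`: features that predict the
outcome dominate the metric. For each menu option the K nearest training
visits of that class are found and their observed outcomes averaged
(unweighted — distance-weighted averaging is a possible refinement, but the
plain mean is the estimator implemented and tested). Choices the estimator
must make that a formula does not dictate:

* **Ties** are broken by ascending visit id — deterministic and
  reproducible.
* **K** defaults to 50; pools smaller than K use all members and flag the
  prediction.
* **Leakage**: a query never draws neighbors from its own patient, extending
  the patient-disjoint split hygiene to in-set predictions.
* **Current-regimen option**: a monotherapy visit's current option *is* that
  class's option (menu size 7); combination and untreated visits get a
  separate `"current"` option predicted from training visits with the
  identical regimen set, falling back — flagged — to the union of the
  constituent classes' pools when fewer than K exact matches exist. The
  metric for a combination uses the constituent class model with the
  largest coefficient mass; untreated regimens use an unweighted metric.

The neighbor search is exact (vectorized full scan); pools at this scale do
not justify approximate indexing, and exactness is verified against a
brute-force oracle.

## Prescription policy

Hard clinical rules prune the menu per visit: pulse < 60 removes
beta-blockers; potassium > 4.5 removes ACEi/ARB; creatinine ≥ 2 removes
ACEi/ARB/thiazide; potassium > 5 removes MRA. An option containing any
contraindicated class — including a combination current regimen — is
removed. Advisory preferences (diabetes → ACEi/ARB, systolic heart failure →
beta-blocker) do not force the choice: they multiply the option's softmax
weight by `soft_preference_weight` (default 1.5; 1 disables), since the
clinical phrasing is "should likely", not "must". Missing rule labs leave
the rule untriggered and mark the visit `rule_unevaluable` — conservative
for efficacy analysis and transparent in the output.

Over the allowed options, option *m* receives probability proportional to
`w_m * exp(-xi * yhat_m)` (max-shifted for numerical stability). The
deterministic mode takes the argmin; the randomized mode draws with a
per-visit seed. `xi` defaults to 0.25 — on the default synthetic cohort this
keeps the randomized policy's mean predicted SBP within about 1 mmHg of the
deterministic policy's while still spreading probability over close
alternatives. The switch threshold `delta` defaults to 0 and the harness can
report results at several values; no particular constant is baked in because
a principled threshold depends on distributional assumptions about the
prediction error that the package does not impose. The keep-current
comparison applies only when the current option is itself allowed: a
contraindicated current regimen is always switched away from. If the rules
exclude everything, the recommendation falls back to the current regimen
with an explicit warning status.

## The synthetic cohort generator

`generate_cohort()` emulates the data-generating process the estimator is
designed for, with every latent quantity exposed:

* **Dynamics**: each patient's mean SBP follows a first-order autoregression
  toward a patient-specific setpoint, `S[t+1] = rho * S[t] + (1 - rho) *
  setpoint + effect(regimen, x) + eta[t]`, with `rho = 0.7`. Setpoints are
  N(150, 12) shifted by age, smoking and diabetes.
* **Treatment effects** are linear in covariates (base class effects of −4
  to −8 mmHg with ±2–3.5 mmHg interactions on diabetes, race, heart
  failure, age), so a linear outcome model is correctly specified and
  recovery is testable; heterogeneity makes the truth-optimal class vary
  across patients. Combination effects are sub-additive (strongest class in
  full, others at 40%).
* **Confounding**: the simulated standard of care assigns drugs by a
  guideline-flavored softmax (diabetics preferentially ACEi/ARB, heart
  failure → beta-blocker, Black patients → CCB/thiazide), initiates
  treatment preferentially at high SBP, and escalates to combinations —so
  observed assignments are confounded with outcomes, as in real
  observational data.
* **Ground truth**: for every evaluable period the counterfactual
  next-period mean SBP is stored for all 7 monotherapies and for
  continuation of the current regimen, *sharing the period's process-noise
  draw*, so at `noise_sd = 0` the observed outcome equals the truth entry of
  the administered option exactly.
* **Mess**: process noise (default 5 mmHg) plus measurement noise (half
  that), entry-error outliers (±50 mmHg shifts on a configurable fraction of
  SBP records, truth untouched), completely-at-random missingness (the
  anchor first-SBP record is always retained so period alignment is
  preserved), and labs calibrated so each clinical rule has triggering
  patients.

What it does **not** emulate: ICD-coded histories, free-text, survey
instruments, informative missingness, dosage, adherence, or measurement
artifacts like white-coat effects. Passing tests on this generator show the
pipeline recovers a *linear, confounded, outlier-contaminated* world; they
cannot certify performance under misspecification real EHRs may exhibit.

## Evaluation harness

`repeated_splits()` runs the full protocol — split, fit, predict, recommend,
score — over repeated seeds and aggregates means and dispersions per
(algorithm, policy mode), alongside two references: the *current regimen*
(predicted outcome of continuing the active prescription) and *standard of
care* (observed outcome under the actual prescription). Reductions are
negative-signed mmHg changes from the current SBP. On synthetic cohorts
every recommendation is additionally re-scored against the generator's truth
table, including a uniform-random-over-allowed-options baseline; comparing
predicted with true reductions makes the optimism of
predicted-outcome-selection visible rather than hidden.

Subgroup analyses mirror the questions a clinical reader would ask:
`deprescribing_analysis()` (combination-therapy visits where the monotherapy
recommendation beats standard of care, with a covariate profile),
`naive_initiation_analysis()` (non-diabetic visits with no antihypertensive
exposure in the current or any earlier period — "drug-naive" has no
universal lookback definition, so the package uses the full observed
history), `neighborhood_profiles()` (feature summaries of the pooled
neighbor sets behind each recommended class, against the test-set baseline),
`aggregate_importance()` (per-model unit-normalized |β| averaged across
sub-models), and `export_dossiers()` (seeded per-case review packets).
`percent_improvement(a, b) = (|a| - |b|)/|b| * 100` is the comparison
arithmetic used throughout.

## Problem sizes and numerical tolerances

The shipped analyses use cohorts of 1,000–2,000 synthetic patients over a
720-day horizon (five 80/10/10 splits, K = 50), sizes at which every
per-class pool is well populated and the full protocol runs comfortably on a
single core; smaller cohorts (60–300 patients) drive the unit tests. Softmax
normalization is checked to 1e-12; the robust solver targets 1e-6 relative
objective and reaches machine precision at `eps = 0` via the interpolation
polish; probability draws, splits, generators and subsamples are all
seed-deterministic.

## Known limitations

Counterfactual predictions inherit the selection optimism of
predicted-outcome argmin policies; the truth-based columns quantify it on
synthetic data, but on real data only a prospective evaluation could.
Rare-class pools (MRA especially) can be too small in modest cohorts, making
their predictions noisy — flagged, but not corrected. The generator's
linearity favors linear learners by construction; CART serves as the
nonlinear comparator, not as evidence about nonlinear real-world structure.
Combination therapy is predicted (as the current-regimen option) but never
*recommended*: the menu is monotherapy plus continuation.
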