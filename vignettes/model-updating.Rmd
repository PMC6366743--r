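---
title: "Updating clinical risk prediction models in a new population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Updating clinical risk prediction models in a new population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskupdate)
```

## The problem

A logistic risk prediction model developed in one population usually
miscalibrates — and often discriminates worse — when applied to another,
because case-mix, outcome prevalence and predictor effects differ between
settings. `riskupdate` implements the standard ladder of remedies for a
published model
$$\operatorname{logit} P(Y = 1 \mid x) = \alpha + \sum_j \beta_j x_j = \mathrm{LP}(x)$$
applied to a new cohort, ordered by how much of the original model each
step discards:

* **Method 0 (external validation).** Apply the published intercept and
  coefficients unchanged.
* **Method 1 (intercept adjustment).** Add a correction factor
  $\Delta = \operatorname{logit}(\bar y) - \operatorname{logit}(\bar p)$
  to the intercept, where $\bar y$ is the observed prevalence and
  $\bar p$ the mean predicted risk. A pure shift of the linear predictor:
  discrimination is mathematically unchanged.
* **Method 2 (logistic calibration).** Fit
  $y \sim a + b\,\mathrm{LP}$ by maximum likelihood. The slope $b$
  (typically $< 1$) uniformly deflates the published coefficients; the
  composed model has intercept $a + b\alpha$ and coefficients $b\beta_j$.
* **Method 3 (revision).** After Method 2, test each model term $x_j$ for
  a population-specific deviation: fit
  $y \sim \operatorname{offset}(a_2 + b_2\,\mathrm{LP}) + \gamma_j x_j$
  and screen $\gamma_j$ with a likelihood-ratio (LR) test. Terms
  significant at $\alpha = 0.05$ enter a joint refit
  $y \sim \alpha^\ast + \beta^\ast \mathrm{LP} + \sum_{j \in S}\gamma_j x_j$.
* **Method 4 (re-estimation).** Refit intercept and all coefficients of
  the original predictor set in the new data, discarding the published
  estimates.
* **Method 5 (extension).** As Method 3, but screening predictors the
  model does not already contain; selected candidates $z_k$ join the
  recalibrated linear predictor with free coefficients $\delta_k$.
* **De novo development.** Backward stepwise logistic regression over the
  full measured-predictor pool, as a ceiling comparator.

Methods 3–5 and the developed model estimate free coefficients in a
modest sample and are therefore shrunk parameterwise (below).

The packaged registry (`load_model_registry()`) carries five published
prevalent-diabetes screening models — Cambridge, Kuwaiti, Omani, Rotterdam
and the simplified Finnish score — declaratively: each term stores its
published log-odds coefficient *and* the rule deriving its design value
from raw fields (sex-specific waist cutoffs, BMI/age bands,
family-history composites). `encode_predictors()` turns any cohort table
into a design matrix, so every updating method works on raw participant
records.

## Estimation details and numerical choices

All logistic fits use iteratively reweighted least squares
(`stats::glm.fit`) with a relative-deviance tolerance of `1e-10` and at
most 100 iterations. Two consequences are used as invariants throughout
the tests: the ML score equation forces the training-set expected/observed
(E/O) ratio of any fitted model to equal 1, and affine recalibration with
positive slope cannot change the C-statistic.

*Separation.* A fitted indicator coefficient beyond ±15 is treated as
(quasi-)separation. Method 4 raises an error naming the offending terms —
with a 1.1% corticosteroid prevalence, a training split of ~720 records
can easily contain no medicated cases — and `run_experiment()` records
such per-cell failures and continues.

*Screening.* Method 3/5 screening fixes both $a_2$ and $b_2$ inside the
offset and frees only the tested term; the final model refits intercept,
slope and selected deviations jointly. Because $a_2, b_2$ are ML-fitted on
the same data, the per-term score is partially absorbed by the offset and
the deviation tests are conservative for terms correlated with the linear
predictor — under the null we measure a familywise selection rate near
zero for Method 3, while Method 5 candidates (independent of the model's
terms) run at their nominal per-test level. Multi-level categorical
candidates (education, smoking, drinking, the BMI band pair) are tested
and selected as whole blocks (df = number of levels − 1).

*Stepwise removal.* Backward selection drops the block with the largest
LR p-value at or above `alpha`, breaking ties toward the block with the
smaller largest absolute standardized coefficient, until all survivors
are significant.

*Parameterwise shrinkage.* For each of `B` (default 200) bootstrap
resamples the free model is refit; its per-term contributions
$\hat\beta_j^{(b)} x_j$ are evaluated on the original sample; and a
logistic calibration regression of the original outcome on those
contribution columns yields one calibration coefficient per term. The
per-term bootstrap means are the shrinkage factors (truncated to
$[0, 1.5]$), the coefficients are multiplied by them, and the intercept is
re-estimated by ML with the shrunk terms as an offset — which restores
training E/O = 1 exactly. With data abundant relative to the parameter
count the factors approach 1; in deliberately overfit settings (ten noise
indicators, n = 120) their mean drops clearly below 1.

*Band conventions.* All bands are encoded as half-open intervals
`[min, next-band-min)` on the continuous scale, so band families are
mutually exclusive and exhaustive; cutoffs printed with ≥ are closed on
the left, and the Kuwaiti waist term (`> 100 cm`) is open on the left.
The Rotterdam "age per 5 years from 55" term is not defined precisely in
its source table; it is encoded as the count of completed 5-year
increments at or above 55 (55 → 1, 60 → 2, …, capped at 5), a documented
convention of this package.

## Why Method 1 uses the moment correction — and what that implies

Two definitions of "intercept adjustment" circulate: the closed-form
moment correction above, and the ML variant that refits only the
intercept with the linear predictor as an offset. The ML variant forces
training E/O = 1 and thereby erases the qualitative distinction between
simple prevalence correction and the ML-fitted Methods 2–5; the moment
correction is the classical closed-form prevalence fix, keeps Method 1
cheap and transparent, and is what `method1_intercept_adjustment()`
computes.

The moment correction has a knowable cost: it matches
$\operatorname{logit}$ of *mean* risks, not the mean of record-level
log-odds, so when the linear predictor is wide it is an inconsistent
estimator of a pure intercept shift (a Jensen-gap effect). In simulations
from a registry model whose intercept is shifted by −1, the mean
recovered correction factor sits at about −0.69 to −0.96 depending on the
model's linear-predictor variance, never exactly −1. The package reports
this property openly rather than silently switching estimators: the
recovery simulation in the test suite asserts the shift at a ±0.1 band
and fails for the moment estimator by construction, while the same
simulations show Method 3 selecting a genuinely drifted coefficient in
90% of runs and Method 4 Wald intervals covering the generating values in
94% of runs.

## The synthetic cohort generator

No participant-level data ship with the package. `generate_cohort()`
emulates a community diabetes-screening sample: 1256 recruited, 173 with
a previous diabetes diagnosis (flagged, never given a screening outcome,
excluded by `exclude_diagnosed()`), age 51.9 (SD 14.9) years, 23.2% male,
BMI 29.7 (7.0) kg/m², waist 95.8 (15.3) cm, SBP 124.3 (20.0) and DBP 76.0
(12.7) mmHg, and the published prevalences for medication use,
family history, alcohol and smoking. Continuous fields are drawn from
truncated-normal marginals (age 20–90, BMI 14–60, WC 50–160, SBP 80–220,
DBP 40–130) coupled by a Gaussian copula with WC~BMI correlation 0.8 and
SBP~DBP 0.6 — plausible values, not published ones, as only marginals are
reported. Category splits not published are fixed defaults: smoking
never/ex/current 0.45/0.15/0.40 (current = the published 40%), drinking
0.599/0.15/0.251, education primary/high-school/university
0.779/0.121/0.10.

The outcome is simulated from a configurable true model — by default the
Omani model with its intercept re-solved by monotone root finding
(`calibrate_true_intercept()`) so the mean predicted risk among
non-excluded records equals the 15% target prevalence. Any registry model
(or a modified copy) can serve as the truth, which is how the
parameter-recovery and null-size simulations work.

Missingness is injected MCAR per field: about 25% in each family-history
flag, 6.1% for smoking, 3% elsewhere; `simple_impute()` substitutes the
observed mean (continuous) or mode (categorical, ties toward the
reference level). Two things the generator deliberately does *not*
emulate: the joint block pattern of family-history missingness in real
interviews (independent masking makes the share of records with at least
one missing value larger than a real cohort's), and any non-MCAR
mechanism. Passing tests therefore demonstrate the correctness of the
pipeline's logic under a clean, known truth — not robustness to
informative missingness or to covariate structure beyond pairwise
correlation.

## Problem sizes used by the test suite

Chosen to make Monte-Carlo error small relative to every asserted margin:
marginal checks at the default n = 1256; prevalence averaged over 50
seeds; logistic-calibration self-consistency at n = 5000; parameter
recovery 100 cohorts of n = 5000; null size control 200 cohorts at the
default size; shrinkage checks at n = 8000 (large-sample limit) and
n = 120 with ten noise terms (overfit regime), B = 60–80 replicates in
tests against an API default of B = 200.

## Known limitations

* The five registry models are transcriptions of their published updated
  forms; re-deriving them from the original source publications
  (including points-based score versions) is out of scope.
* The E/O confidence interval uses the log-scale Poisson approximation
  `ratio * exp(±1.96/√O)` by default — the standard closed form for
  standardized event ratios; exact chi-square Poisson bounds are
  available via `exact = TRUE`.
* DeLong placement variances are computed with an O(n·m) outer product —
  fine for cohort-scale data, not tuned for very large n.
* Bootstrap shrinkage factors are noisy below B ≈ 50 (a warning is
  issued); they are means of calibration regressions, not penalized
  estimates, and can exceed 1 (truncated at 1.5).

## A minimal end-to-end run

```{r example, eval = FALSE}
cfg <- experiment_config(models = c("cambridge", "omani"),
                         shrinkage_B = 200,
                         seeds = list(cohort = 1, split = 2, bootstrap = 3))
bundle <- run_experiment(cfg)
bundle$performance[, c("model", "method", "dataset", "eo", "c", "brier")]
render_tables(bundle, "results")
render_calibration_grid(bundle, "results")
```
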