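---
title: "Smoothed O/E benchmarking of broad-spectrum antibiotic use: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smoothed O/E benchmarking: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimand and the model

Hospitals are compared on broad-spectrum antibiotic exposure during
empiric pneumonia treatment — whether a patient received any of 26
reserved agents (`broad_spectrum_agents()`) within the first 48 hours of
admission. Raw use rates confound practice style with case mix, so the
comparison runs through a patient-level risk model with a hospital
random intercept: for patient $i$ in hospital $j$,

$$\mathrm{logit}(p_{ij}) = \alpha + x_{ij}'\beta + \gamma_j,
\qquad \gamma_j \sim N(0, \sigma^2).$$

The benchmarking statistic is the **smoothed O/E ratio**

$$\widehat{OE}_j \;=\;
\frac{\sum_i \mathrm{invlogit}(\hat\alpha + x_{ij}'\hat\beta + \hat\gamma_j)}
     {\sum_i \mathrm{invlogit}(\hat\alpha + x_{ij}'\hat\beta)},$$

whose numerator (the "smoothed observed" use) replaces the raw event
count of the crude O/E with the model's with-intercept predictions. The
posterior-mode $\hat\gamma_j$ is shrunk toward 0 in proportion to how
little data hospital $j$ contributes, so small hospitals cannot reach
extreme ratios on sampling noise alone. A ratio above 1 means more use
than expected for that hospital's case mix.

Assumptions worth keeping in mind: a single Gaussian random intercept
(no random slopes, no hospital-level fixed covariates), logistic link,
and patient-level predictors only. Both ratios share a denominator built
from the population-average (intercept-free) predictions, so a
hospital's own deviation never enters its expectation.

## Cohort selection

The selection cascade mirrors the target study design, in this order:
inclusion (age $\ge$ 65, pneumonia ICD-10 families J13–J18, antibiotics
within 48 h), exclusion of surgery-before-treatment admissions
(perioperative prophylaxis) and of records missing any risk-adjustment
field (complete case), then exclusion of hospitals with fewer than 100
total cases. "Over 64 years old" is implemented as integer age $\ge$ 65.
The 100-case cutoff is strict (`< 100` drops, `= 100` stays) and is
evaluated on the post-exclusion analyzable counts — the record-level
filters are row-local predicates and commute, but the hospital-level
cutoff depends on what survives them, so it runs last. The missing-data
check uses exactly the model's predictor fields
(`risk_adjustment_fields()`), one shared constant, so the filter and the
design matrix can never disagree.

## Predictor coding

The model names its severity inputs but administrative data carry them
as continuous measurements, so the package dichotomizes at the published
A-DROP criteria: BUN $\ge$ 21 mg/dL, SpO2 $\le$ 90%, systolic BP
$\le$ 90 mmHg; orientation disturbance is already a flag. These cutoffs
live in one editable block (`adrop_thresholds()`). Age enters
continuously, centered at 65 and scaled to decades (`(age - 65) / 10`)
— the cohort restriction already handles the A-DROP age criterion, and
decade scaling keeps the optimizer well conditioned. ICD-10 pneumonia
families are indicator-coded against J18 (pneumonia, organism
unspecified), by far the most frequent family in administrative coding,
which makes the reference the "typical" admission. Whether the original
analysis entered severity linearly or dichotomized, and which reference
it used, is not documented; both choices are config-exposed
(`model_spec()`).

## Estimation

`fit_random_intercept_logistic()` maximizes the marginal likelihood with
lme4's `glmer`: `quadrature_order` maps to `nAGQ` (default 7; 1 is the
Laplace fast path used for the larger simulations in this package's own
scripts). Fitting is deterministic — no random initialization — which
makes the pipeline's byte-identical rerun contract possible.
$\hat\gamma_j$ are the conditional (posterior) modes. The reported
`loglik` is recomputed at the optimum by the package's own adaptive
Gauss–Hermite evaluator (`marginal_loglik()`, order 50, Golub–Welsch
nodes, mode-centered and curvature-scaled per cluster), so it does not
depend on the `nAGQ` used for optimization; the test suite checks it
against an independent non-adaptive 50-point quadrature.

Degenerate inputs: a constant outcome or a single cluster is an error;
runaway coefficients (|log-odds| > 15) are treated as evidence of
quasi-separation and raise an error by default, or a warning with
`on_separation = "warn"` — the latter matters for bootstrap replicates
of small cohorts, where a resampled rare flag (e.g. pulmonary
circulation disorder at 1% prevalence) can separate by chance. No
penalized fallback is provided; the intended data regime (hundreds of
events per hospital) makes separation of the full fit implausible.

## Validation battery

`performance_table()` reports, per temporal split (training fiscal
year, validation fiscal year, pooled): C-statistic with and without the
hospital intercept, mean observed vs mean predicted, calibration slope,
and accuracy at a 0.5 threshold (config-exposed; the choice is
conventional, not derived). The C-statistic uses the midrank
Mann–Whitney identity, ties counting one half. The calibration slope is
the MLE slope of outcome on logit(prediction). Validation-split
predictions carry the training $\hat\gamma_j$; hospitals unseen in
training predict at $\gamma = 0$ (population average), and the policy is
recorded on the prediction object. Scalar metrics use the
with-intercept predictions by default (`use_random = FALSE` switches),
since those are the predictions the benchmarking statistic consumes.

## Bootstrap confidence intervals

The uncertainty statement is a within-hospital patient bootstrap:
patients are resampled with replacement inside each hospital (the
hospital set is fixed — hospitals are the objects under comparison, not
a sample), the model is refitted per replicate, and per-hospital 95%
intervals are order-statistic percentiles of the replicate smoothed
O/E values. Refitting propagates estimation uncertainty in
$(\hat\alpha, \hat\beta, \hat\sigma, \hat\gamma)$; a `refit = FALSE`
variant re-predicts from the original fit and only propagates case-mix
resampling — it is much cheaper and clearly labeled, but its intervals
are too narrow for inference and suit smoke tests and null-control
checks. Replicates whose refit fails are dropped with a warning; more
than 10% failures aborts. Order-statistic (type 1) quantiles make the
degenerate `B = 2` interval exactly the two replicate values.
Categorization against 1 uses strict inequalities; boundary equality
counts as crossing.

## The synthetic-cohort generator

The inpatient database this method targets is access restricted, so the
generator (`cohort_config()` / `generate_cohort()`) emulates its
structure: hospitals with negative-binomial caseloads (default mean
255, matching ~245k admissions over ~958 hospitals), two fiscal years
assigned 53/47, covariates drawn independently given the hospital from
marginals loosely imitating the published cohort profile (mean age 81,
SD 8.3; 41.7% female; plausible comorbidity prevalences), continuous
severity fields drawn from truncated normals and dichotomized
downstream, and the outcome drawn from the logistic model above. The
default intercept $\alpha = -1.145$ was calibrated once by large-n
Monte Carlo so the marginal prevalence matches the published 35.3% use
rate; the default $\sigma = 0.5$ gives a with/without-intercept
C-statistic gap similar to the published one (0.722 vs 0.632). Default
coefficient magnitudes follow the direction of the published univariate
patterns (ventilation and ICU strongest).

Exclusion-trigger records (prior surgery, no antibiotics, age $\le$ 64,
non-pneumonia codes, masked severity fields) are generated as *extra*
rows on top of the analyzable caseload, so tests can assert exact
survivor counts. The random stream is partitioned by hospital then
patient (one derived seed per hospital), so the same config is
byte-identical and adding hospitals never perturbs earlier ones.

What the generator does **not** emulate: covariate correlations (none
are published; independence is the simplest structure that exercises
every model term), ICD-10 detail beyond the pneumonia families,
drug-level exposure, seasonal or temporal drift between fiscal years,
and hospital-level covariates. Passing tests therefore demonstrate
correctness of the machinery and recoverability under the assumed model
— not that real inter-hospital variation is as well behaved.

## Numerical choices and scales

Tests and scripts run at desk scale, chosen to finish in minutes while
leaving the statistical checks well powered: parameter recovery at 200
hospitals × mean 250 patients (where $\hat\sigma$ lands within ±0.1 of
0.5 and posterior modes correlate with truth at r > 0.9), the null
control at 100 × 200 with a 200-iteration no-refit bootstrap, the
refit-bootstrap checks at a few thousand admissions. The tiny
quadrature-oracle fixtures (≤ 3 hospitals, ≤ 30 patients) are small
enough for a dense $(\alpha, \sigma)$ grid search over an independent
50-point quadrature to serve as ground truth. `true_oe_ratios()`
exposes the generator-truth estimand so recovery is tested against what
the statistic actually targets, not against raw rates.

## Known limitations

- The bootstrap resamples patients, not hospitals; it quantifies
  within-hospital sampling noise, not uncertainty about the hospital
  population.
- With many hospitals genuinely away from O/E = 1 (any $\sigma > 0$),
  CI-versus-1 flags are expected to mark a large share of hospitals;
  they are descriptions of precision, not multiplicity-adjusted tests.
- Posterior modes, not means, define the smoothed numerator; at
  $\sigma \le 1$ the difference is negligible relative to sampling
  noise.
- The generator's marginals are plausible, not estimates; no claim of
  distributional fidelity to any real cohort is made.
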