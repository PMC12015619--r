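# oebench

Risk-adjusted benchmarking of broad-spectrum antibiotic use across
hospitals, via smoothed observed-to-expected (O/E) ratios.

## The problem

Antimicrobial stewardship programs need to compare hospitals on how much
they use broad-spectrum antibiotics (carbapenems, anti-MRSA agents,
antipseudomonal beta-lactams, ...), but raw use rates are confounded by
case mix: a hospital admitting sicker pneumonia patients should use more.
The standard remedy is the observed-to-expected ratio — observed use over
the use predicted by a patient-level risk model — but the crude O/E is
noisy for small hospitals. This package implements the *smoothed* O/E
ratio for the empiric treatment (first 48 h) of pneumonia in older-adult
inpatients: the numerator is itself a model-based estimate that shrinks
small-sample noise toward the risk-adjusted average.

It is aimed at health-services researchers and stewardship analysts who
want a tested, reproducible implementation of the whole pipeline —
cohort selection, multilevel risk model, validation battery, and
hospital league table — plus a synthetic-cohort generator, since the
national inpatient databases this method is designed for are access
restricted.

## The model

For patient *i* in hospital *j*, broad-spectrum exposure within 48 h of
admission is modeled as

```
logit(p_ij) = alpha + x_ij' beta + gamma_j,   gamma_j ~ N(0, sigma^2)
```

where `x_ij` holds age, sex, ICD-10 pneumonia family, the A-DROP
severity components (BUN >= 21 mg/dL, SpO2 <= 90%, orientation
disturbance, SBP <= 90 mmHg), care-setting flags (ICU, ventilator,
admission source, tube feeding, immunodeficiency, recent
hospitalization) and ten comorbidities. `gamma_j` is the hospital random
intercept, estimated by maximum marginal likelihood (adaptive
Gauss–Hermite quadrature via lme4). Per hospital:

```
smoothed O/E_j = sum_i invlogit(alpha + x_ij' beta + gamma_j)   /
                 sum_i invlogit(alpha + x_ij' beta)
```

95% CIs come from a within-hospital patient bootstrap (percentile
method); hospitals are categorized as *below* (upper CI < 1), *above*
(lower CI > 1) or *crossing* 1.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on a
synthetic cohort (60 hospitals, ~17k admissions) and write their tables
under `results/analysis/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_filter_cohort.R
Rscript analysis/03_fit_model.R
Rscript analysis/04_validate_model.R
Rscript analysis/05_benchmark_hospitals.R
```

Output from a run:

```
simulated 17094 admissions across 60 hospitals
crude broad-spectrum use: 35.3% (target 35.3%)
...
  after <100-case hospital cutoff:  14100
  hospitals: 60 -> 49
...
hospital-intercept sd: 0.532 (generator truth 0.5)
...
  c_statistic_with_re      train 0.684 | validation 0.667 | overall 0.676
  c_statistic_without_re   train 0.624 | validation 0.619 | overall 0.622
...
  smoothed O/E range: 0.42 - 1.61
  below / crossing / above 1: 25 / 0 / 24
  cor(log smoothed O/E, true hospital intercept): 0.961
```

Reading the numbers: the generator's true hospital SD (0.5) is recovered
at 0.53; the C-statistic gains ~0.06 when the hospital intercept is
included, i.e. hospitals differ beyond case mix; the league table spans
O/E 0.42–1.61 and log smoothed O/E tracks the true hospital intercepts
at r = 0.96.

The same steps are available as one call:

```r
library(oebench)
res <- run_pipeline(list(cohort = cohort_config(n_hospitals = 60),
                         bootstrap = list(B = 500, refit = FALSE, seed = 1),
                         out_dir = "results/pipeline"))
```

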