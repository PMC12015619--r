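#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic admission cohort.
#
# The DPC inpatient database behind the original analysis is restricted, so
# the workflow runs on a synthetic cohort with the same statistical
# structure: hospital-clustered admissions, patient-level risk factors, a
# Gaussian hospital intercept (sd 0.5 on the log-odds scale), and a
# marginal broad-spectrum-use prevalence calibrated to 35.3%. Scaled to 60
# hospitals so the full workflow runs in minutes.

suppressPackageStartupMessages(library(oebench))

out_dir <- "results/analysis"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- cohort_config(n_hospitals = 60, seed = 20240401L)
write_cohort_config(cfg, file.path(out_dir, "cohort_config.yaml"))

cohort <- generate_cohort(cfg)
write_cohort_csv(cohort, file.path(out_dir, "cohort_raw.csv"))

gammas <- attr(cohort, "gammas")
write.csv(data.frame(hospital_id = names(gammas), true_gamma = gammas,
                     row.names = NULL),
          file.path(out_dir, "true_gammas.csv"), row.names = FALSE)

cat(sprintf("simulated %d admissions across %d hospitals\n",
            nrow(cohort), cfg$n_hospitals))
cat(sprintf("crude broad-spectrum use: %.1f%% (target 35.3%%)\n",
            100 * mean(cohort$broad_spectrum_use)))
cat(sprintf("fiscal years: %s\n",
            paste(names(table(cohort$fiscal_year)),
                  table(cohort$fiscal_year), collapse = ", ")))
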