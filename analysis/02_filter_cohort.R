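#!/usr/bin/env Rscript
# Stage 2: apply the study selection cascade.
#
# Inclusion: age >= 65, pneumonia ICD-10 (J13-J18), antibiotics within the
# first 48 h of admission. Exclusion: surgery before treatment
# (perioperative prophylaxis), incomplete risk-adjustment data, and
# hospitals with fewer than 100 total cases.

suppressPackageStartupMessages(library(oebench))

out_dir <- "results/analysis"
cohort <- read_cohort_csv(file.path(out_dir, "cohort_raw.csv"))

filtered <- filter_cohort(cohort, min_cases = 100)
write_cohort_csv(filtered$records, file.path(out_dir, "cohort_analyzable.csv"))
jsonlite::write_json(filtered$report,
                     file.path(out_dir, "filter_report.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

r <- filtered$report
cat("selection cascade:\n")
cat(sprintf("  initial records:                  %d\n", r$initial))
cat(sprintf("  after age/ICD/antibiotic filter:  %d\n",
            r$after_age_icd_abx_inclusion))
cat(sprintf("  after surgery exclusion:          %d\n",
            r$after_surgery_exclusion))
cat(sprintf("  after complete-case exclusion:    %d\n",
            r$after_missing_exclusion))
cat(sprintf("  after <100-case hospital cutoff:  %d\n",
            r$after_small_hospital_exclusion))
cat(sprintf("  hospitals: %d -> %d\n", r$hospitals_initial,
            r$hospitals_final))
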