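#' Inclusion step: older-adult pneumonia admissions on early antibiotics
#'
#' Keeps admissions of patients over 64 years old (age >= 65), with a
#' pneumonia diagnosis (ICD-10 J13, J14, J15.x, J16.x, J17.x, J18.x), who
#' received antibiotic treatment within the first 48 hours. Row order is
#' preserved; `age`, `icd10` and `abx_within_48h` are required and never
#' missing by construction.
#'
#' @param records cohort data.frame.
#' @return The included records.
#' @export
apply_inclusion <- function(records) {
  keep <- records$age >= 65 &
    substr(records$icd10, 1, 3) %in% pneumonia_icd10_codes() &
    records$abx_within_48h == 1L
  records[keep, , drop = FALSE]
}

#' Exclusion step: prior surgery and incomplete risk-adjustment data
#'
#' Removes admissions with surgery before antibiotic treatment (treated as
#' perioperative prophylaxis) and admissions missing any field needed for
#' risk adjustment (complete-case analysis over
#' [risk_adjustment_fields()]).
#'
#' @param records cohort data.frame (inclusion already applied).
#' @return The surviving records.
#' @export
apply_exclusions <- function(records) {
  keep <- records$surgery_before_treatment != 1L &
    stats::complete.cases(records[, risk_adjustment_fields(), drop = FALSE])
  records[keep, , drop = FALSE]
}

#' Exclude hospitals with fewer than `min_cases` total cases
#'
#' The threshold is strict: a hospital with exactly `min_cases` cases
#' (counted across both fiscal years, after the record-level filters) is
#' kept.
#'
#' @param records cohort data.frame (record-level filters applied).
#' @param min_cases minimum total caseload, default 100.
#' @return Records of the surviving hospitals.
#' @export
exclude_small_hospitals <- function(records, min_cases = 100) {
  if (min_cases < 1) stop("min_cases must be >= 1")
  counts <- table(records$hospital_id)
  keep_hosp <- names(counts)[counts >= min_cases]
  records[records$hospital_id %in% keep_hosp, , drop = FALSE]
}

#' Non-random temporal split by fiscal year
#'
#' @param records cohort data.frame.
#' @param train_label,valid_label the two fiscal-year labels.
#' @return List with elements `train` and `validation`; their union is the
#'   input and their intersection empty.
#' @export
split_by_fiscal_year <- function(records, train_label = "FY2018",
                                 valid_label = "FY2019") {
  unknown <- setdiff(unique(records$fiscal_year),
                     c(train_label, valid_label))
  if (length(unknown) > 0)
    stop("unknown fiscal-year labels present: ",
         paste(unknown, collapse = ", "))
  list(train = records[records$fiscal_year == train_label, , drop = FALSE],
       validation = records[records$fiscal_year == valid_label, , drop = FALSE])
}

#' Full selection cascade with a stage-count report
#'
#' Applies, in order: inclusion (age / diagnosis / early antibiotics),
#' surgery exclusion, complete-case exclusion, then the small-hospital
#' exclusion — the flow-diagram ordering, with the hospital-level cutoff
#' evaluated on the post-exclusion analyzable counts.
#'
#' @param records cohort data.frame.
#' @param min_cases hospital caseload cutoff (see
#'   [exclude_small_hospitals()]).
#' @return List with `records` (final analyzable set) and `report`, a list
#'   of stage counts: `initial`, `after_age_icd_abx_inclusion`,
#'   `after_surgery_exclusion`, `after_missing_exclusion`,
#'   `after_small_hospital_exclusion`, `hospitals_initial`,
#'   `hospitals_final`.
#' @export
filter_cohort <- function(records, min_cases = 100) {
  s0 <- records
  s1 <- apply_inclusion(s0)
  s2 <- s1[s1$surgery_before_treatment != 1L, , drop = FALSE]
  s3 <- s2[stats::complete.cases(
    s2[, risk_adjustment_fields(), drop = FALSE]), , drop = FALSE]
  s4 <- exclude_small_hospitals(s3, min_cases)
  report <- list(
    initial = nrow(s0),
    after_age_icd_abx_inclusion = nrow(s1),
    after_surgery_exclusion = nrow(s2),
    after_missing_exclusion = nrow(s3),
    after_small_hospital_exclusion = nrow(s4),
    hospitals_initial = length(unique(s0$hospital_id)),
    hospitals_final = length(unique(s4$hospital_id))
  )
  list(records = s4, report = report)
}
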