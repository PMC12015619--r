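#' Broad-spectrum antibiotic agent catalog
#'
#' The 26 agents treated as broad-spectrum (reserved for suspected
#' multidrug-resistant pathogens) when coding the patient-level exposure
#' outcome: carbapenems, anti-MRSA agents, antipseudomonal beta-lactams,
#' respiratory fluoroquinolones and last-line agents.
#'
#' @return Character vector of 26 agent names.
#' @export
broad_spectrum_agents <- function() {
  c(
    "Aztreonam", "Biapenem", "Cefepime", "Cefozopran",
    "Ceftolozane-Tazobactam", "Ciprofloxacin", "Colistin", "Daptomycin",
    "Doripenem", "Faropenem", "Fosfomycin", "Imipenem", "Lascufloxacin",
    "Linezolid", "Meropenem", "Minocycline", "Panipenem", "Pazufloxacin",
    "Piperacillin-Tazobactam", "Polymyxin B", "Prulifloxacin", "Tebipenem",
    "Tedizolid", "Teicoplanin", "Tigecycline", "Vancomycin"
  )
}

#' Validate a broad-spectrum agent catalog
#'
#' @param agents character vector of agent names.
#' @return The catalog, invisibly, after validation.
#' @export
validate_catalog <- function(agents) {
  if (length(agents) == 0) stop("agent catalog must be non-empty")
  if (anyDuplicated(tolower(agents)))
    stop("agent names must be unique (case-insensitive)")
  invisible(agents)
}

#' Pneumonia ICD-10 code families used for inclusion
#'
#' @return Character vector of 3-character ICD-10 prefixes.
#' @export
pneumonia_icd10_codes <- function() {
  c("J13", "J14", "J15", "J16", "J17", "J18")
}

#' A-DROP severity dichotomization thresholds
#'
#' Cutoffs used to turn the continuous severity measurements into the
#' binary A-DROP components: dehydration (BUN >= 21 mg/dL), respiratory
#' failure (SpO2 <= 90%), hypotension (systolic BP <= 90 mmHg).
#' Orientation disturbance is recorded directly as a flag.
#'
#' @return Named list with elements `bun`, `spo2`, `sbp`.
#' @export
adrop_thresholds <- function() {
  list(bun = 21, spo2 = 90, sbp = 90)
}

#' Raw record fields required for risk adjustment
#'
#' The complete-case (missing-data) exclusion checks exactly these fields;
#' the same list drives the design matrix, so the filter and the model can
#' never disagree about what "missing risk-adjustment data" means.
#'
#' @return Character vector of column names.
#' @export
risk_adjustment_fields <- function() {
  c(
    "age", "sex", "icd10", "bun", "spo2", "orientation_disturbance", "sbp",
    "immunodeficiency", "prior_hosp_90d", "admit_from_home",
    "admit_from_nursing_home", "icu", "ventilator", "tube_feeding",
    comorbidity_fields()
  )
}

#' Comorbidity flag fields
#' @return Character vector of comorbidity column names.
#' @export
comorbidity_fields <- function() {
  c(
    "chf", "hypertension", "copd", "diabetes", "dementia",
    "cerebrovascular", "renal", "rheumatic", "cancer", "pulm_circ"
  )
}

# Fields the generator may mask to trigger the complete-case exclusion.
# age / icd10 / abx_within_48h are never maskable: inclusion needs them.
maskable_fields <- function() c("bun", "spo2", "sbp")

invlogit <- stats::plogis
logit <- stats::qlogis
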