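#' Default generative coefficients (log odds ratios)
#'
#' Conditional (within-hospital) log odds ratios for broad-spectrum
#' antibiotic use, keyed by design-matrix column. Magnitudes follow the
#' direction and rough strength of the univariate patterns reported for
#' the real cohort (mechanical ventilation and ICU admission carry the
#' largest effects; female sex and dementia mildly protective).
#'
#' @return Named numeric vector.
#' @export
default_true_beta <- function() {
  c(
    age_dec = 0.05, sex = -0.15,
    icd10J13 = -0.30, icd10J14 = -0.20, icd10J15 = 0.45,
    icd10J16 = 0.10, icd10J17 = 0.20,
    bun_high = 0.25, spo2_low = 0.35, orientation_disturbance = 0.30,
    sbp_low = 0.40,
    immunodeficiency = 0.60, prior_hosp_90d = 0.40,
    admit_from_home = -0.20, admit_from_nursing_home = 0.25,
    icu = 0.60, ventilator = 1.10, tube_feeding = 0.35,
    chf = 0.10, hypertension = -0.05, copd = 0.15, diabetes = 0.10,
    dementia = -0.10, cerebrovascular = 0.10, renal = 0.30,
    rheumatic = 0.25, cancer = 0.20, pulm_circ = 0.20
  )
}

#' Default covariate marginal model
#'
#' Marginal distributions for the admission-level covariates, mutually
#' independent given the hospital. Continuous severity measurements (BUN,
#' SpO2, SBP) are drawn continuous from truncated normals and dichotomized
#' downstream at the A-DROP thresholds; `icd10` and `admit_origin` are
#' categorical draws feeding multiple design indicators.
#'
#' @return Named list of per-field specs.
#' @export
default_covariate_model <- function() {
  list(
    age_dec = list(type = "truncnorm", field = "age",
                   mean = 81, sd = 8.3, lower = 65, upper = 106),
    sex = list(type = "binary", p = 0.417),
    icd10 = list(type = "categorical",
                 levels = c("J13", "J14", "J15", "J16", "J17", "J18"),
                 probs = c(0.02, 0.01, 0.15, 0.02, 0.03, 0.77)),
    bun_high = list(type = "truncnorm", field = "bun",
                    mean = 20, sd = 9, lower = 0, upper = 150),
    spo2_low = list(type = "truncnorm", field = "spo2",
                    mean = 94, sd = 4, lower = 50, upper = 100),
    orientation_disturbance = list(type = "binary", p = 0.13),
    sbp_low = list(type = "truncnorm", field = "sbp",
                   mean = 125, sd = 22, lower = 40, upper = 260),
    immunodeficiency = list(type = "binary", p = 0.04),
    prior_hosp_90d = list(type = "binary", p = 0.18),
    admit_origin = list(type = "categorical",
                        levels = c("home", "nursing_home", "other"),
                        probs = c(0.75, 0.18, 0.07)),
    icu = list(type = "binary", p = 0.03),
    ventilator = list(type = "binary", p = 0.03),
    tube_feeding = list(type = "binary", p = 0.08),
    chf = list(type = "binary", p = 0.15),
    hypertension = list(type = "binary", p = 0.35),
    copd = list(type = "binary", p = 0.12),
    diabetes = list(type = "binary", p = 0.20),
    dementia = list(type = "binary", p = 0.25),
    cerebrovascular = list(type = "binary", p = 0.15),
    renal = list(type = "binary", p = 0.08),
    rheumatic = list(type = "binary", p = 0.03),
    cancer = list(type = "binary", p = 0.12),
    pulm_circ = list(type = "binary", p = 0.01)
  )
}

#' Cohort generator configuration
#'
#' Parameters of the synthetic hospital-clustered admission cohort. The
#' defaults emulate the study conditions: heterogeneous hospital caseloads
#' (negative binomial, mean 255 as in ~245k admissions over ~958 hospitals),
#' two fiscal years split roughly 53/47, hospital random-intercept SD 0.5 on
#' the log-odds scale, and an intercept calibrated so the marginal
#' prevalence of broad-spectrum use is 35.3%.
#'
#' @param n_hospitals number of hospitals.
#' @param caseload_law distribution of per-hospital analyzable caseloads:
#'   list with `family` ("nbinom", "fixed", or "given"), `mean` and `size`
#'   (dispersion) for nbinom, or `counts` (one per hospital) for "given".
#'   Draws are truncated at 1.
#' @param fy_labels ordered fiscal-year labels (length >= 2).
#' @param fy_probs membership probabilities for `fy_labels` (sums to 1).
#' @param true_alpha model intercept (log-odds).
#' @param true_beta named log-odds coefficients; keys must map into
#'   `covariate_model` (icd10 indicator keys map to the `icd10` entry,
#'   admission-origin indicator keys to `admit_origin`).
#' @param sigma_re SD of the hospital random intercept (log-odds scale).
#' @param covariate_model per-field marginal specs, see
#'   [default_covariate_model()].
#' @param missing_rate,surgery_rate,no_abx_rate,underage_rate,nonpneumonia_rate
#'   rates of exclusion-trigger records, generated as extra rows on top of
#'   the analyzable caseload so filter survivor counts are exact.
#' @param seed integer seed; the stream is partitioned by hospital then
#'   patient, so growing `n_hospitals` never perturbs earlier hospitals.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_hospitals = 100,
                          caseload_law = list(family = "nbinom",
                                              mean = 255, size = 1.8),
                          fy_labels = c("FY2018", "FY2019"),
                          fy_probs = c(0.5295, 0.4705),
                          true_alpha = -1.145,
                          true_beta = default_true_beta(),
                          sigma_re = 0.5,
                          covariate_model = default_covariate_model(),
                          missing_rate = 0.02,
                          surgery_rate = 0.02,
                          no_abx_rate = 0.05,
                          underage_rate = 0.05,
                          nonpneumonia_rate = 0.03,
                          seed = 1L) {
  config <- list(
    n_hospitals = as.integer(n_hospitals), caseload_law = caseload_law,
    fy_labels = fy_labels, fy_probs = fy_probs,
    true_alpha = true_alpha, true_beta = true_beta, sigma_re = sigma_re,
    covariate_model = covariate_model,
    missing_rate = missing_rate, surgery_rate = surgery_rate,
    no_abx_rate = no_abx_rate, underage_rate = underage_rate,
    nonpneumonia_rate = nonpneumonia_rate, seed = as.integer(seed)
  )
  class(config) <- "cohort_config"
  validate_cohort_config(config)
}

#' Validate a cohort configuration
#'
#' @param config a `cohort_config` list.
#' @return The config, invisibly usable, after checking every invariant;
#'   errors name the offending field.
#' @export
validate_cohort_config <- function(config) {
  stop_cfg <- function(field, msg)
    stop(sprintf("invalid cohort config: `%s` %s", field, msg), call. = FALSE)

  if (!is.numeric(config$n_hospitals) || config$n_hospitals < 1)
    stop_cfg("n_hospitals", "must be a positive integer")
  if (!is.numeric(config$sigma_re) || config$sigma_re < 0)
    stop_cfg("sigma_re", "must be non-negative")
  for (field in c("missing_rate", "surgery_rate", "no_abx_rate",
                  "underage_rate", "nonpneumonia_rate")) {
    p <- config[[field]]
    if (!is.numeric(p) || p < 0 || p >= 1)
      stop_cfg(field, "must be a probability in [0, 1)")
  }
  if (length(config$fy_labels) < 1 || anyDuplicated(config$fy_labels))
    stop_cfg("fy_labels", "must be non-empty and unique")
  if (length(config$fy_probs) != length(config$fy_labels) ||
      abs(sum(config$fy_probs) - 1) > 1e-8 || any(config$fy_probs < 0))
    stop_cfg("fy_probs", "must be non-negative and sum to 1, one per label")
  fam <- config$caseload_law$family
  if (!fam %in% c("nbinom", "fixed", "given"))
    stop_cfg("caseload_law", "family must be 'nbinom', 'fixed' or 'given'")
  if (fam == "given") {
    if (length(config$caseload_law$counts) != config$n_hospitals)
      stop_cfg("caseload_law", "needs one count per hospital")
  } else if (!is.numeric(config$caseload_law$mean) ||
             config$caseload_law$mean < 1) {
    stop_cfg("caseload_law", "mean must be >= 1")
  }

  for (key in names(config$true_beta)) {
    if (is.null(resolve_covariate_entry(key, config$covariate_model)))
      stop_cfg("true_beta",
               sprintf("key '%s' has no matching covariate_model entry", key))
  }
  if (is.null(config$seed)) stop_cfg("seed", "must be provided")
  config
}

# icd10 indicator coefficients map to the single categorical icd10 entry;
# admission-origin indicators map to admit_origin.
resolve_covariate_entry <- function(key, covariate_model) {
  if (key %in% names(covariate_model)) return(covariate_model[[key]])
  if (grepl("^icd10", key)) return(covariate_model[["icd10"]])
  if (key %in% c("admit_from_home", "admit_from_nursing_home"))
    return(covariate_model[["admit_origin"]])
  NULL
}

#' Write / read a cohort configuration as YAML
#'
#' Round-trips losslessly: numeric, character and nested list fields are
#' preserved.
#'
#' @param config a `cohort_config`.
#' @param path file path.
#' @return `write_cohort_config` returns `path` invisibly;
#'   `read_cohort_config` returns a validated `cohort_config`.
#' @export
write_cohort_config <- function(config, path) {
  out <- unclass(config)
  out$true_beta <- as.list(config$true_beta)  # keep names in the YAML map
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  config <- yaml::read_yaml(path)
  config$n_hospitals <- as.integer(config$n_hospitals)
  config$seed <- as.integer(config$seed)
  config$true_beta <- unlist(config$true_beta)
  class(config) <- "cohort_config"
  validate_cohort_config(config)
}
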