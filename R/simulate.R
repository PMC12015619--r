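#' Generate a synthetic hospital-clustered pneumonia admission cohort
#'
#' Draws one Gaussian random intercept per hospital, admission-level
#' covariates from the configured marginals, and the binary broad-spectrum
#' antibiotic use outcome from the logistic model
#' `logit(p_ij) = alpha + x_ij' beta + gamma_j`. Exclusion-trigger records
#' (prior surgery, no antibiotics within 48 h, age <= 64, non-pneumonia
#' diagnosis, masked severity fields) are appended as extra rows on top of
#' the analyzable caseload, so the filter cascade recovers the analyzable
#' count exactly.
#'
#' The random stream is partitioned deterministically by hospital then
#' patient index: the same config yields byte-identical output, and adding
#' hospitals does not perturb earlier hospitals' draws. The caller's RNG
#' state is left untouched.
#'
#' @param config a [cohort_config()].
#' @return A data.frame of admission records (one row per admission) with
#'   attributes `gammas` (named vector of the true hospital intercepts) and
#'   `config`.
#' @export
generate_cohort <- function(config) {
  config <- validate_cohort_config(config)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old_seed), add = TRUE)

  pieces <- vector("list", config$n_hospitals)
  gammas <- numeric(config$n_hospitals)
  hosp_ids <- sprintf("H%04d", seq_len(config$n_hospitals))
  names(gammas) <- hosp_ids

  for (j in seq_len(config$n_hospitals)) {
    set.seed(hospital_seed(config$seed, j))
    gammas[j] <- stats::rnorm(1, 0, config$sigma_re)
    n_core <- draw_caseload(config$caseload_law, j)
    pieces[[j]] <- simulate_hospital(config, hosp_ids[j], gammas[j], n_core)
  }

  cohort <- do.call(rbind, pieces)
  rownames(cohort) <- NULL
  attr(cohort, "gammas") <- gammas
  attr(cohort, "config") <- config
  cohort
}

restore_rng <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

hospital_seed <- function(seed, j) {
  as.integer((as.numeric(seed) + 1000003 * j) %% 2147483629)
}

draw_caseload <- function(law, j) {
  n <- switch(law$family,
    nbinom = stats::rnbinom(1, size = law$size, mu = law$mean),
    fixed  = law$mean,
    given  = law$counts[j],
    stop("unknown caseload family: ", law$family)
  )
  max(1L, as.integer(n))
}

simulate_hospital <- function(config, hosp_id, gamma_j, n_core) {
  extra_counts <- vapply(
    c("surgery_rate", "no_abx_rate", "underage_rate", "nonpneumonia_rate",
      "missing_rate"),
    function(r) stats::rbinom(1, n_core, config[[r]]), integer(1))
  n_total <- n_core + sum(extra_counts)

  rec <- draw_covariates(n_total, config$covariate_model)
  rec$fiscal_year <- sample(config$fy_labels, n_total, replace = TRUE,
                            prob = config$fy_probs)
  rec$surgery_before_treatment <- 0L
  rec$abx_within_48h <- 1L

  kind <- rep(c("core", "surgery", "no_abx", "underage", "nonpneumonia",
                "missing"),
              times = c(n_core, extra_counts))

  # Trigger-specific mutations. Outcomes are computed afterwards from the
  # complete covariates; masking happens last so the outcome model never
  # sees an NA.
  n_under <- extra_counts[["underage_rate"]]
  if (n_under > 0)
    rec$age[kind == "underage"] <- sample(40:64, n_under, replace = TRUE)
  n_nonpneu <- extra_counts[["nonpneumonia_rate"]]
  if (n_nonpneu > 0)
    rec$icd10[kind == "nonpneumonia"] <-
      sample(c("A41.9", "J44.1", "I50.9"), n_nonpneu, replace = TRUE)
  rec$surgery_before_treatment[kind == "surgery"] <- 1L
  rec$abx_within_48h[kind == "no_abx"] <- 0L

  eta <- config$true_alpha +
    linear_predictor_raw(rec, config$true_beta) + gamma_j
  rec$broad_spectrum_use <- stats::rbinom(n_total, 1, invlogit(eta))
  rec$broad_spectrum_use[rec$abx_within_48h == 0L] <- 0L

  n_missing <- extra_counts[["missing_rate"]]
  if (n_missing > 0) {
    fields <- sample(maskable_fields(), n_missing, replace = TRUE)
    rows <- which(kind == "missing")
    for (i in seq_len(n_missing)) rec[rows[i], fields[i]] <- NA_real_
  }

  rec$hospital_id <- hosp_id
  rec$patient_id <- sprintf("%s-P%05d", hosp_id, seq_len(n_total))
  front <- c("patient_id", "hospital_id", "fiscal_year")
  rec[, c(front, setdiff(names(rec), front))]
}

draw_covariates <- function(n, covariate_model) {
  out <- list()
  for (key in names(covariate_model)) {
    spec <- covariate_model[[key]]
    if (spec$type == "binary") {
      out[[key]] <- stats::rbinom(n, 1, spec$p)
    } else if (spec$type == "truncnorm") {
      u <- stats::runif(n,
                        stats::pnorm(spec$lower, spec$mean, spec$sd),
                        stats::pnorm(spec$upper, spec$mean, spec$sd))
      out[[spec$field]] <- stats::qnorm(u, spec$mean, spec$sd)
    } else if (spec$type == "categorical") {
      out[[key]] <- sample(spec$levels, n, replace = TRUE, prob = spec$probs)
    } else {
      stop("unknown covariate spec type: ", spec$type)
    }
  }
  rec <- as.data.frame(out, stringsAsFactors = FALSE)
  rec$age <- as.integer(round(rec$age))
  # icd10 subcode for families coded with a decimal in ICD-10
  sub <- rec$icd10 %in% c("J15", "J16", "J17", "J18")
  if (any(sub))
    rec$icd10[sub] <- paste0(rec$icd10[sub], ".",
                             sample(0:9, sum(sub), replace = TRUE))
  rec$admit_from_home <- as.integer(rec$admit_origin == "home")
  rec$admit_from_nursing_home <- as.integer(rec$admit_origin == "nursing_home")
  rec$admit_origin <- NULL
  rec
}

# Lenient linear predictor used by the generator and the ground-truth
# oracle: unknown ICD-10 codes contribute the reference (zero) effect so
# exclusion-trigger rows still get an outcome.
linear_predictor_raw <- function(records, beta) {
  thr <- adrop_thresholds()
  icd <- substr(records$icd10, 1, 3)
  vals <- list(
    age_dec = (records$age - 65) / 10,
    sex = records$sex,
    icd10J13 = as.numeric(icd == "J13"),
    icd10J14 = as.numeric(icd == "J14"),
    icd10J15 = as.numeric(icd == "J15"),
    icd10J16 = as.numeric(icd == "J16"),
    icd10J17 = as.numeric(icd == "J17"),
    bun_high = as.numeric(records$bun >= thr$bun),
    spo2_low = as.numeric(records$spo2 <= thr$spo2),
    orientation_disturbance = records$orientation_disturbance,
    sbp_low = as.numeric(records$sbp <= thr$sbp)
  )
  for (f in c("immunodeficiency", "prior_hosp_90d", "admit_from_home",
              "admit_from_nursing_home", "icu", "ventilator", "tube_feeding",
              comorbidity_fields()))
    vals[[f]] <- records[[f]]
  eta <- numeric(nrow(records))
  for (key in names(beta)) {
    if (is.null(vals[[key]]))
      stop("true_beta key with no generated covariate: ", key)
    eta <- eta + beta[[key]] * vals[[key]]
  }
  eta
}

#' Ground-truth smoothed O/E ratios from the generative parameters
#'
#' The estimand the smoothed O/E ratio targets, computed from the TRUE
#' generator parameters: per hospital, the sum of event probabilities with
#' the hospital's random intercept divided by the sum without it.
#'
#' @param config the [cohort_config()] that produced `records`.
#' @param gammas named vector of true hospital intercepts (the `gammas`
#'   attribute of [generate_cohort()] output).
#' @param records admission records for which to evaluate the ratio.
#' @return Named numeric vector, one ratio per hospital present in
#'   `records`.
#' @export
true_oe_ratios <- function(config, gammas, records) {
  hospitals <- unique(records$hospital_id)
  absent <- setdiff(hospitals, names(gammas))
  if (length(absent) > 0)
    stop("hospitals absent from drawn gammas: ",
         paste(absent, collapse = ", "))
  eta0 <- config$true_alpha + linear_predictor_raw(records, config$true_beta)
  eta1 <- eta0 + gammas[records$hospital_id]
  num <- tapply(invlogit(eta1), records$hospital_id, sum)
  den <- tapply(invlogit(eta0), records$hospital_id, sum)
  ratio <- as.numeric(num / den)
  names(ratio) <- names(num)
  ratio[hospitals]
}
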