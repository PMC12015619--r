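# Shared fixtures and independent oracles for the test suite.

# A small, fast cohort configuration; override any field via ...
small_config <- function(n_hospitals = 15, mean_caseload = 120,
                         sigma_re = 0.5, seed = 11,
                         caseload_law = list(family = "nbinom",
                                             mean = mean_caseload,
                                             size = 5), ...) {
  cohort_config(n_hospitals = n_hospitals, caseload_law = caseload_law,
                sigma_re = sigma_re, seed = seed, ...)
}

# A clean cohort with no exclusion-trigger rows at all.
clean_config <- function(..., missing_rate = 0, surgery_rate = 0,
                         no_abx_rate = 0, underage_rate = 0,
                         nonpneumonia_rate = 0) {
  small_config(missing_rate = missing_rate, surgery_rate = surgery_rate,
               no_abx_rate = no_abx_rate, underage_rate = underage_rate,
               nonpneumonia_rate = nonpneumonia_rate, ...)
}

toy_records <- function() {
  read_cohort_csv(system.file("extdata", "toy_admissions.csv",
                              package = "oebench"))
}

glmm_tiny <- function() {
  utils::read.csv(system.file("extdata", "glmm_tiny.csv",
                              package = "oebench"),
                  stringsAsFactors = FALSE)
}

# --- Independent oracles -------------------------------------------------

# Non-adaptive 50-point Gauss-Hermite marginal log-likelihood for the
# intercept-only random-intercept model (oracle route: pracma's nodes,
# no adaptive re-centering — independent of the package's evaluator).
oracle_loglik_gh50 <- function(alpha, sigma, y, cluster) {
  gh <- pracma::gaussHermite(50)
  if (sigma == 0)
    return(sum(stats::dbinom(y, 1, stats::plogis(alpha), log = TRUE)))
  total <- 0
  for (ix in split(seq_along(y), cluster)) {
    yi <- y[ix]
    vals <- vapply(gh$x, function(x) {
      p <- stats::plogis(alpha + sqrt(2) * sigma * x)
      exp(sum(stats::dbinom(yi, 1, p, log = TRUE)))
    }, numeric(1))
    total <- total + log(sum(gh$w * vals) / sqrt(pi))
  }
  total
}

# Dense two-stage grid search maximizing the oracle likelihood.
oracle_grid_fit <- function(y, cluster) {
  ll <- function(a, s) oracle_loglik_gh50(a, s, y, cluster)
  coarse <- expand.grid(alpha = seq(-3, 3, by = 0.05),
                        sigma = seq(0, 2, by = 0.05))
  vals <- mapply(ll, coarse$alpha, coarse$sigma)
  best <- coarse[which.max(vals), ]
  fine <- expand.grid(alpha = seq(best$alpha - 0.06, best$alpha + 0.06,
                                  by = 0.002),
                      sigma = seq(max(0, best$sigma - 0.06),
                                  best$sigma + 0.06, by = 0.002))
  fvals <- mapply(ll, fine$alpha, fine$sigma)
  top <- fine[which.max(fvals), ]
  list(alpha = top$alpha, sigma = top$sigma, loglik = max(fvals))
}

# Exhaustive pairwise concordance (quadratic; ties count one half).
oracle_c_statistic <- function(y, p) {
  pos <- p[y == 1]; neg <- p[y == 0]
  total <- 0
  for (a in pos) total <- total + sum(a > neg) + 0.5 * sum(a == neg)
  total / (length(pos) * length(neg))
}

# Univariate logistic MLE by Newton iteration on (intercept, slope):
# independent of stats::glm.
oracle_calibration_slope <- function(y, p) {
  x <- cbind(1, stats::qlogis(p))
  b <- c(0, 0)
  for (i in 1:50) {
    mu <- stats::plogis(x %*% b)
    W <- as.numeric(mu * (1 - mu))
    step <- solve(t(x) %*% (x * W), t(x) %*% (y - mu))
    b <- b + step
    if (max(abs(step)) < 1e-12) break
  }
  b[2]
}

# Minimal complete record template for hand-built fixtures.
blank_records <- function(n) {
  rec <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    hospital_id = "H1", fiscal_year = "FY2018",
    age = 80L, sex = 0L, icd10 = "J18.9",
    bun = 15, spo2 = 96, orientation_disturbance = 0L, sbp = 130,
    immunodeficiency = 0L, prior_hosp_90d = 0L,
    admit_from_home = 1L, admit_from_nursing_home = 0L,
    icu = 0L, ventilator = 0L, tube_feeding = 0L,
    surgery_before_treatment = 0L, abx_within_48h = 1L,
    broad_spectrum_use = 0L,
    stringsAsFactors = FALSE
  )
  for (f in comorbidity_fields()) rec[[f]] <- 0L
  rec
}
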