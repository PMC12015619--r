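#' Risk-adjustment model specification
#'
#' Defines the predictor coding and fitting controls for the
#' hospital-clustered random-intercept logistic model. Continuous severity
#' fields are dichotomized at the A-DROP thresholds; age enters continuous
#' in decades over 65; ICD-10 pneumonia families are indicator-coded
#' against a stated reference (J18, unspecified pneumonia, by far the most
#' frequent code in administrative data).
#'
#' @param icd10_reference reference ICD-10 family (default "J18").
#' @param cluster_field name of the clustering column.
#' @param quadrature_order adaptive Gauss-Hermite order passed to the
#'   fitter; 1 is the Laplace fast path. Default 7.
#' @param tol convergence tolerance for the fixed-point checks.
#' @param max_iter optimizer evaluation budget.
#' @param accuracy_threshold classification threshold used by the
#'   validation battery.
#' @param on_separation "error" (default) or "warn" when runaway
#'   coefficients suggest perfect separation.
#' @return A `model_spec` list.
#' @export
model_spec <- function(icd10_reference = "J18",
                       cluster_field = "hospital_id",
                       quadrature_order = 7,
                       tol = 1e-6,
                       max_iter = 100000,
                       accuracy_threshold = 0.5,
                       on_separation = c("error", "warn")) {
  if (quadrature_order < 1) stop("quadrature_order must be >= 1")
  spec <- list(
    icd10_reference = icd10_reference,
    cluster_field = cluster_field,
    quadrature_order = as.integer(quadrature_order),
    tol = tol, max_iter = max_iter,
    accuracy_threshold = accuracy_threshold,
    on_separation = match.arg(on_separation)
  )
  class(spec) <- "model_spec"
  spec
}

#' Build the design matrix and outcome vector
#'
#' Deterministic column order: age (decades over 65), sex, ICD-10
#' indicators against the reference family, the four A-DROP components
#' (BUN >= 21 mg/dL, SpO2 <= 90%, orientation disturbance, SBP <= 90 mmHg),
#' care-setting flags, then comorbidity flags. Records must be
#' complete-case for every predictor (the filter cascade guarantees this).
#'
#' @param records cohort data.frame.
#' @param spec a [model_spec()].
#' @return List with `X` (numeric matrix), `y` (0/1 outcome vector) and
#'   `cluster` (factor of hospital ids).
#' @export
build_design <- function(records, spec = model_spec()) {
  miss <- setdiff(risk_adjustment_fields(), names(records))
  if (length(miss) > 0)
    stop("records lack predictor fields: ", paste(miss, collapse = ", "))
  sub <- records[, risk_adjustment_fields(), drop = FALSE]
  if (anyNA(sub)) {
    bad <- names(sub)[vapply(sub, anyNA, logical(1))]
    stop("missing values in predictor fields (filters should have removed ",
         "them): ", paste(bad, collapse = ", "))
  }

  icd <- substr(records$icd10, 1, 3)
  known <- pneumonia_icd10_codes()
  if (any(!icd %in% known))
    stop("unseen ICD-10 categories: ",
         paste(unique(records$icd10[!icd %in% known]), collapse = ", "))
  icd_levels <- setdiff(known, spec$icd10_reference)

  thr <- adrop_thresholds()
  cols <- list(
    age_dec = (records$age - 65) / 10,
    sex = as.numeric(records$sex)
  )
  for (lv in icd_levels) cols[[paste0("icd10", lv)]] <- as.numeric(icd == lv)
  cols$bun_high <- as.numeric(records$bun >= thr$bun)
  cols$spo2_low <- as.numeric(records$spo2 <= thr$spo2)
  cols$orientation_disturbance <- as.numeric(records$orientation_disturbance)
  cols$sbp_low <- as.numeric(records$sbp <= thr$sbp)
  for (f in c("immunodeficiency", "prior_hosp_90d", "admit_from_home",
              "admit_from_nursing_home", "icu", "ventilator", "tube_feeding",
              comorbidity_fields()))
    cols[[f]] <- as.numeric(records[[f]])

  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X,
       y = as.integer(records$broad_spectrum_use),
       cluster = factor(records[[spec$cluster_field]]))
}

#' Fit the random-intercept logistic risk-adjustment model
#'
#' Approximate maximum marginal likelihood via lme4's adaptive
#' Gauss-Hermite quadrature (`nAGQ = quadrature_order`; order 1 is the
#' Laplace approximation). The per-hospital intercept predictions are the
#' conditional (posterior) modes at the optimum. Fitting is deterministic:
#' no random initialization anywhere.
#'
#' @param X design matrix from [build_design()].
#' @param y 0/1 outcome vector.
#' @param cluster factor of hospital ids.
#' @param spec a [model_spec()].
#' @return A `risk_model_fit` list: `alpha` (fixed intercept), `beta`
#'   (named fixed effects), `sigma2` (random-intercept variance),
#'   `gamma_hat` (named posterior modes, one per hospital), `loglik`
#'   (approximate marginal log-likelihood), `converged`, `n_obs`,
#'   `n_hospitals`, `beta_se`, plus the underlying lme4 fit in `$engine`.
#' @export
fit_random_intercept_logistic <- function(X, y, cluster, spec = model_spec()) {
  if (nlevels(droplevels(factor(cluster))) < 2)
    stop("need at least 2 clusters to fit a random intercept")
  if (length(unique(y)) < 2)
    stop("outcome is constant; the model is not identifiable")

  cols <- colnames(X) %||% character(0)
  df <- if (length(cols)) as.data.frame(X) else
    data.frame(row.names = seq_along(y))
  df$.y <- y
  df$.cluster <- droplevels(factor(cluster))
  form <- stats::reformulate(c(cols, "(1 | .cluster)"), response = ".y")
  ctrl <- lme4::glmerControl(
    optimizer = "bobyqa",
    optCtrl = list(maxfun = spec$max_iter),
    calc.derivs = FALSE)
  fit <- suppressMessages(
    lme4::glmer(form, data = df, family = stats::binomial(),
                nAGQ = spec$quadrature_order, control = ctrl))

  fe <- lme4::fixef(fit)
  if (any(abs(fe) > 15)) {
    msg <- "runaway coefficients suggest (quasi-)separation"
    if (spec$on_separation == "error") stop(msg) else warning(msg)
  }
  re <- lme4::ranef(fit)$.cluster
  gamma_hat <- stats::setNames(re[["(Intercept)"]], rownames(re))
  vc <- as.data.frame(lme4::VarCorr(fit))
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  alpha <- unname(fe[["(Intercept)"]])
  beta <- fe[setdiff(names(fe), "(Intercept)")]
  sigma2 <- vc$vcov[1]
  # reported marginal log-likelihood: high-order adaptive quadrature at
  # the optimum, independent of the nAGQ used for fitting
  ll <- marginal_loglik(alpha, beta, sqrt(sigma2), X, y, df$.cluster,
                        order = max(50L, spec$quadrature_order))

  structure(list(
    alpha = alpha,
    beta = beta,
    beta_se = stats::setNames(se[-1], setdiff(names(fe), "(Intercept)")),
    sigma2 = sigma2,
    gamma_hat = gamma_hat,
    loglik = ll,
    converged = length(fit@optinfo$conv$lme4$messages) == 0 &&
      fit@optinfo$conv$opt == 0,
    n_obs = length(y),
    n_hospitals = nlevels(df$.cluster),
    spec = spec,
    engine = fit
  ), class = "risk_model_fit")
}

#' Convenience wrapper: design + fit from raw records
#'
#' @param records complete-case cohort data.frame.
#' @param spec a [model_spec()].
#' @return A `risk_model_fit` (see [fit_random_intercept_logistic()]).
#' @export
fit_risk_model <- function(records, spec = model_spec()) {
  d <- build_design(records, spec)
  fit_random_intercept_logistic(d$X, d$y, d$cluster, spec)
}

#' @export
print.risk_model_fit <- function(x, ...) {
  cat(sprintf(
    "Random-intercept logistic fit: %d obs, %d hospitals\n", x$n_obs,
    x$n_hospitals))
  cat(sprintf("  sigma^2 = %.4f (sigma = %.4f), logLik = %.2f, %s\n",
              x$sigma2, sqrt(x$sigma2), x$loglik,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Predicted probabilities with or without the hospital intercept
#'
#' @param fit a `risk_model_fit`.
#' @param X design matrix with the same columns the fit used.
#' @param cluster hospital ids for each row.
#' @param include_random include the predicted hospital intercepts? A
#'   hospital unseen in training gets `gamma = 0` (population-average
#'   prediction); the policy and the affected hospitals are recorded on the
#'   result.
#' @return List with `prob` (vector strictly in (0,1)), `include_random`,
#'   `unseen_policy`, `unseen_hospitals`.
#' @export
predict_risk <- function(fit, X, cluster, include_random = TRUE) {
  cn <- colnames(X) %||% character(0)
  if (!identical(cn, names(fit$beta) %||% character(0)))
    stop("design columns do not match the fitted model")
  eta <- rep(fit$alpha, nrow(X)) +
    (if (length(cn)) as.numeric(X %*% fit$beta) else 0)
  unseen <- character(0)
  if (include_random) {
    cl <- as.character(cluster)
    g <- fit$gamma_hat[cl]
    unseen <- unique(cl[is.na(g)])
    g[is.na(g)] <- 0
    eta <- eta + unname(g)
  }
  list(prob = invlogit(eta),
       include_random = include_random,
       unseen_policy = "gamma = 0",
       unseen_hospitals = unseen)
}

#' Variance inflation factors
#'
#' `VIF_k = 1 / (1 - R^2_k)` with `R^2_k` from the linear regression of
#' column `k` on all other columns (with intercept). Columns involved in an
#' exact linear dependence get `Inf` rather than an error.
#'
#' @param X design matrix (>= 2 columns).
#' @return Named vector of VIFs.
#' @export
compute_vif <- function(X) {
  if (ncol(X) < 2) stop("VIF needs at least 2 columns")
  vif <- vapply(seq_len(ncol(X)), function(k) {
    fit <- stats::lm.fit(cbind(1, X[, -k, drop = FALSE]), X[, k])
    tss <- sum((X[, k] - mean(X[, k]))^2)
    rss <- sum(fit$residuals^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  stats::setNames(vif, colnames(X))
}

#' Serialize a fitted model to JSON
#'
#' Coefficients, variance, per-hospital intercepts and convergence
#' metadata; the lme4 engine object is not serialized.
#'
#' @param fit a `risk_model_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(fit, path) {
  out <- fit[c("alpha", "beta", "beta_se", "sigma2", "gamma_hat", "loglik",
               "converged", "n_obs", "n_hospitals")]
  out$beta <- as.list(out$beta)
  out$beta_se <- as.list(out$beta_se)
  out$gamma_hat <- as.list(out$gamma_hat)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
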