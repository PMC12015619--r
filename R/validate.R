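#' Concordance statistic (C-statistic / AUROC)
#'
#' Probability that a uniformly chosen (positive, negative) pair is ranked
#' concordantly by the predictions, ties counting one half. Computed by the
#' midrank (Mann-Whitney) method in O(n log n); equal by construction to
#' exhaustive pair enumeration.
#'
#' @param outcomes 0/1 vector containing both classes.
#' @param probabilities numeric predictions (any monotone score works).
#' @return C-statistic in \[0, 1\].
#' @export
c_statistic <- function(outcomes, probabilities) {
  stopifnot(length(outcomes) == length(probabilities))
  n1 <- sum(outcomes == 1)
  n0 <- sum(outcomes == 0)
  if (n1 == 0 || n0 == 0)
    stop("C-statistic undefined: outcomes contain a single class")
  r <- rank(probabilities, ties.method = "average")
  (sum(r[outcomes == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Calibration slope
#'
#' Slope of the univariate logistic regression of the outcome on the logit
#' of the predicted probability (free intercept), fitted by maximum
#' likelihood. A slope of 1 indicates well-calibrated spread; below 1,
#' overconfident (too extreme) predictions.
#'
#' @param outcomes 0/1 vector containing both classes.
#' @param probabilities predictions strictly in (0, 1).
#' @return The slope (a real number).
#' @export
calibration_slope <- function(outcomes, probabilities) {
  if (any(probabilities <= 0 | probabilities >= 1))
    stop("probabilities must be strictly in (0, 1)")
  lp <- logit(probabilities)
  fit <- stats::glm(outcomes ~ lp, family = stats::binomial())
  if (!fit$converged) stop("calibration-slope fit did not converge")
  unname(stats::coef(fit)[2])
}

#' Classification accuracy at a probability threshold
#'
#' @param outcomes 0/1 vector.
#' @param probabilities numeric predictions.
#' @param threshold classification cutoff in (0, 1), default 0.5.
#' @return Fraction of records whose thresholded prediction equals the
#'   outcome.
#' @export
accuracy <- function(outcomes, probabilities, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)")
  mean(as.integer(probabilities >= threshold) == outcomes)
}

#' TRIPOD-style performance table across temporal splits
#'
#' Computes, for the training, validation and overall (concatenated)
#' datasets: the C-statistic with and without the hospital random
#' intercept, mean observed outcome, mean predicted probability, the
#' calibration slope, and accuracy. Validation-split predictions carry the
#' training-fit hospital intercepts; hospitals unseen in training get
#' `gamma = 0`. Mean predicted, calibration slope and accuracy use the
#' with-intercept predictions unless `use_random = FALSE`.
#'
#' @param fit a `risk_model_fit` trained on the training split.
#' @param train training-split records.
#' @param valid validation-split records (may be empty).
#' @param spec the [model_spec()] used for the fit.
#' @param use_random use with-intercept predictions for the scalar metrics.
#' @return Data.frame with one row per metric and one column per split;
#'   cells that cannot be computed (empty split) are NA.
#' @export
performance_table <- function(fit, train, valid, spec = model_spec(),
                              use_random = TRUE) {
  split_metrics <- function(records) {
    if (is.null(records) || nrow(records) == 0)
      return(c(n = 0, c_statistic_with_re = NA, c_statistic_without_re = NA,
               mean_observed = NA, mean_predicted = NA,
               calibration_slope = NA, accuracy = NA))
    d <- build_design(records, spec)
    p_with <- predict_risk(fit, d$X, d$cluster, include_random = TRUE)$prob
    p_without <- predict_risk(fit, d$X, d$cluster, include_random = FALSE)$prob
    p <- if (use_random) p_with else p_without
    c(n = nrow(records),
      c_statistic_with_re = c_statistic(d$y, p_with),
      c_statistic_without_re = c_statistic(d$y, p_without),
      mean_observed = mean(d$y),
      mean_predicted = mean(p),
      calibration_slope = calibration_slope(d$y, p),
      accuracy = accuracy(d$y, p, spec$accuracy_threshold))
  }
  overall <- rbind(train, valid)
  m <- cbind(train = split_metrics(train),
             validation = split_metrics(valid),
             overall = split_metrics(overall))
  data.frame(metric = rownames(m), m, row.names = NULL)
}
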