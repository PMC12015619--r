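#' Crude observed-to-expected ratio per hospital
#'
#' Observed broad-spectrum use counts divided by the expected count from
#' the risk-adjustment model without the hospital intercept:
#' `sum(y_ij) / sum(invlogit(alpha + x_ij' beta))`.
#'
#' @param fit a `risk_model_fit`.
#' @param records complete-case records whose hospitals are all known to
#'   the fit (or treated as population-average).
#' @param spec the [model_spec()] used for the fit.
#' @return Named numeric vector, one ratio per hospital.
#' @export
crude_oe <- function(fit, records, spec = model_spec()) {
  d <- build_design(records, spec)
  expected <- predict_risk(fit, d$X, d$cluster, include_random = FALSE)$prob
  num <- tapply(d$y, d$cluster, sum)
  den <- tapply(expected, d$cluster, sum)
  ratio <- as.numeric(num) / as.numeric(den)
  stats::setNames(ratio, names(num))
}

#' Smoothed observed-to-expected ratio per hospital
#'
#' The numerator replaces the raw counts by the model's with-intercept
#' predictions — the smoothed observed use — shrinking small-sample noise
#' toward the risk-adjusted average:
#' `sum(invlogit(alpha + x'beta + gamma_j)) / sum(invlogit(alpha + x'beta))`.
#'
#' @inheritParams crude_oe
#' @return Named numeric vector, one ratio per hospital.
#' @export
smoothed_oe <- function(fit, records, spec = model_spec()) {
  d <- build_design(records, spec)
  smoothed <- predict_risk(fit, d$X, d$cluster, include_random = TRUE)$prob
  expected <- predict_risk(fit, d$X, d$cluster, include_random = FALSE)$prob
  num <- tapply(smoothed, d$cluster, sum)
  den <- tapply(expected, d$cluster, sum)
  ratio <- as.numeric(num) / as.numeric(den)
  stats::setNames(ratio, names(num))
}

#' Cluster bootstrap confidence intervals for the smoothed O/E ratio
#'
#' Resamples patients with replacement within each hospital (the hospital
#' set itself is fixed), recomputes every hospital's smoothed O/E per
#' replicate, and returns per-hospital percentile intervals
#' (order-statistic quantiles, so `B = 2` spans exactly the two replicate
#' values). With `refit = TRUE` (default) the random-intercept model is
#' refitted on every replicate, propagating estimation uncertainty; the
#' cheaper `refit = FALSE` variant re-predicts from the original fit and
#' only propagates case-mix resampling.
#'
#' Replicates whose refit fails are dropped with a warning; more than 10%
#' failures is an error. Deterministic given `seed`.
#'
#' @param records complete-case analyzable records.
#' @param spec the [model_spec()] to fit with.
#' @param fit the original `risk_model_fit` (required when
#'   `refit = FALSE`).
#' @param B number of bootstrap iterations (study default 500).
#' @param level confidence level in (0, 1).
#' @param seed integer seed.
#' @param refit refit the model on each replicate?
#' @return List: `ci` data.frame (hospital_id, ci_lower, ci_upper),
#'   `replicates` (B x hospitals matrix, failed rows dropped), `B_effective`.
#' @export
bootstrap_oe_ci <- function(records, spec = model_spec(), fit = NULL,
                            B = 500, level = 0.95, seed = 1L,
                            refit = TRUE) {
  if (B < 2) stop("B must be >= 2")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  if (!refit && is.null(fit))
    stop("refit = FALSE requires the original fit")

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old_seed), add = TRUE)
  set.seed(as.integer(seed))

  hospitals <- sort(unique(records$hospital_id))
  idx_by_hosp <- split(seq_len(nrow(records)), records$hospital_id)[hospitals]

  reps <- matrix(NA_real_, nrow = B, ncol = length(hospitals),
                 dimnames = list(NULL, hospitals))
  failures <- 0L
  for (b in seq_len(B)) {
    idx <- unlist(lapply(idx_by_hosp,
                         function(ix) ix[sample.int(length(ix),
                                                    length(ix),
                                                    replace = TRUE)]),
                  use.names = FALSE)
    rb <- records[idx, , drop = FALSE]
    ratio <- tryCatch({
      fb <- if (refit) fit_risk_model(rb, spec) else fit
      smoothed_oe(fb, rb, spec)
    }, error = function(e) {
      warning("bootstrap replicate ", b, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(ratio)) failures <- failures + 1L
    else reps[b, names(ratio)] <- ratio
  }
  if (failures > 0.10 * B)
    stop("more than 10% of bootstrap replicates failed (", failures,
         " of ", B, ")")
  reps <- reps[stats::complete.cases(reps), , drop = FALSE]

  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qs <- apply(reps, 2, stats::quantile, probs = probs, type = 1)
  list(ci = data.frame(hospital_id = hospitals,
                       ci_lower = qs[1, ], ci_upper = qs[2, ],
                       row.names = NULL),
       replicates = reps,
       B_effective = nrow(reps))
}

#' Per-hospital benchmarking table
#'
#' Assembles caseload, observed count, smoothed numerator, expected
#' denominator, crude and smoothed O/E, and (when supplied) bootstrap CIs
#' and the CI-versus-1 category.
#'
#' @inheritParams crude_oe
#' @param ci optional CI data.frame from [bootstrap_oe_ci()]`$ci`.
#' @return Data.frame, one row per hospital.
#' @export
hospital_oe <- function(fit, records, spec = model_spec(), ci = NULL) {
  d <- build_design(records, spec)
  smoothed <- predict_risk(fit, d$X, d$cluster, include_random = TRUE)$prob
  expected <- predict_risk(fit, d$X, d$cluster, include_random = FALSE)$prob
  tab <- data.frame(
    hospital_id = levels(d$cluster),
    n = as.integer(table(d$cluster)),
    observed_count = as.integer(tapply(d$y, d$cluster, sum)),
    smoothed_observed = as.numeric(tapply(smoothed, d$cluster, sum)),
    expected = as.numeric(tapply(expected, d$cluster, sum)),
    row.names = NULL
  )
  tab$crude_oe <- tab$observed_count / tab$expected
  tab$smoothed_oe <- tab$smoothed_observed / tab$expected
  if (!is.null(ci)) {
    tab <- merge(tab, ci, by = "hospital_id", all.x = TRUE, sort = TRUE)
    tab$category <- categorize_oe(tab$ci_lower, tab$ci_upper)
  }
  tab
}

#' Categorize hospitals by their CI position relative to 1
#'
#' `below` when the upper CI bound is strictly under 1 (use lower than the
#' risk-adjusted average), `above` when the lower bound is strictly over 1,
#' `crossing` otherwise (boundary equality counts as crossing).
#'
#' @param ci_lower,ci_upper CI bounds.
#' @return Character vector of labels.
#' @export
categorize_oe <- function(ci_lower, ci_upper) {
  ifelse(ci_upper < 1, "below", ifelse(ci_lower > 1, "above", "crossing"))
}

#' Count hospitals per category
#'
#' @param categories labels from [categorize_oe()].
#' @return Named integer vector (below, crossing, above); sums to the
#'   number of hospitals.
#' @export
categorize_counts <- function(categories) {
  vapply(c("below", "crossing", "above"),
         function(k) sum(categories == k), integer(1))
}

#' Pooled smoothed O/E ratio for hospital groups
#'
#' Pools (not averages): per group, the sum of the member hospitals'
#' smoothed numerators divided by the sum of their expected denominators.
#' Used for e.g. teaching-status comparisons.
#'
#' @inheritParams crude_oe
#' @param groups named vector mapping every hospital id to a group label.
#' @return Named numeric vector of group ratios.
#' @export
group_oe <- function(fit, records, groups, spec = model_spec()) {
  hospitals <- unique(records$hospital_id)
  unassigned <- setdiff(hospitals, names(groups))
  if (length(unassigned) > 0)
    stop("hospitals without a group assignment: ",
         paste(unassigned, collapse = ", "))
  d <- build_design(records, spec)
  smoothed <- predict_risk(fit, d$X, d$cluster, include_random = TRUE)$prob
  expected <- predict_risk(fit, d$X, d$cluster, include_random = FALSE)$prob
  g <- groups[as.character(d$cluster)]
  num <- tapply(smoothed, g, sum)
  den <- tapply(expected, g, sum)
  ratio <- as.numeric(num) / as.numeric(den)
  stats::setNames(ratio, names(num))
}

#' Caterpillar-plot export table
#'
#' Hospitals sorted ascending by smoothed O/E (ties broken by hospital
#' id), with rank, point estimate, CI bounds and category — the data
#' behind a league-table caterpillar chart.
#'
#' @param oe_table data.frame from [hospital_oe()] (CIs included).
#' @return Data.frame with columns rank, hospital_id, smoothed_oe,
#'   ci_lower, ci_upper, category.
#' @export
caterpillar_export <- function(oe_table) {
  ord <- order(oe_table$smoothed_oe, oe_table$hospital_id)
  out <- oe_table[ord, , drop = FALSE]
  cols <- intersect(c("hospital_id", "smoothed_oe", "ci_lower", "ci_upper",
                      "category"), names(out))
  out <- out[, cols, drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
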