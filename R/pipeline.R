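#' End-to-end benchmarking pipeline
#'
#' Runs simulate (skipped when `cohort_csv` is supplied) -> filter -> fit
#' -> validate -> benchmark, writing every artifact to `out_dir`:
#' `cohort.csv` (when simulated), `filter_report.json`, `model_fit.json`,
#' `validation.csv`, `hospital_oe.csv`, `caterpillar.csv` and
#' `manifest.json` (stage counts and the seeds used; no timestamps, so a
#' rerun with the same config is byte-identical).
#'
#' @param config list with elements:
#'   \describe{
#'     \item{cohort}{a [cohort_config()], required unless `cohort_csv` given.}
#'     \item{cohort_csv}{optional path to an existing cohort CSV.}
#'     \item{filter}{list(min_cases, train_fy, valid_fy).}
#'     \item{model}{a [model_spec()] (default `model_spec()`).}
#'     \item{bootstrap}{list(B, level, seed, refit).}
#'     \item{out_dir}{output directory, created if absent.}
#'   }
#' @return Invisibly, a list with the in-memory artifacts (records, fit,
#'   validation table, hospital table, manifest).
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("pipeline config needs `out_dir`")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fcfg <- utils::modifyList(
    list(min_cases = 100, train_fy = "FY2018", valid_fy = "FY2019"),
    config$filter %||% list())
  bcfg <- utils::modifyList(
    list(B = 500, level = 0.95, seed = 1L, refit = TRUE),
    config$bootstrap %||% list())
  spec <- config$model %||% model_spec()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  if (!is.null(config$cohort_csv)) {
    records <- stage("load", read_cohort_csv(config$cohort_csv))
  } else {
    if (is.null(config[["cohort"]])) stop("need `cohort` config or `cohort_csv`")
    records <- stage("simulate", generate_cohort(config[["cohort"]]))
    write_cohort_csv(records, file.path(out_dir, "cohort.csv"))
  }

  filtered <- stage("filter", filter_cohort(records, fcfg$min_cases))
  jsonlite::write_json(filtered$report,
                       file.path(out_dir, "filter_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  splits <- stage("split", split_by_fiscal_year(filtered$records,
                                                fcfg$train_fy,
                                                fcfg$valid_fy))
  fit <- stage("fit", fit_risk_model(splits$train, spec))
  write_model_json(fit, file.path(out_dir, "model_fit.json"))

  vtab <- stage("validate",
                performance_table(fit, splits$train, splits$validation, spec))
  utils::write.csv(vtab, file.path(out_dir, "validation.csv"),
                   row.names = FALSE)

  # Benchmarking uses the model refitted on the full analyzable dataset.
  full_fit <- stage("benchmark-fit", fit_risk_model(filtered$records, spec))
  boot <- stage("benchmark-boot",
                bootstrap_oe_ci(filtered$records, spec, fit = full_fit,
                                B = bcfg$B, level = bcfg$level,
                                seed = bcfg$seed, refit = bcfg$refit))
  oe_tab <- stage("benchmark",
                  hospital_oe(full_fit, filtered$records, spec,
                              ci = boot$ci))
  utils::write.csv(oe_tab, file.path(out_dir, "hospital_oe.csv"),
                   row.names = FALSE)
  utils::write.csv(caterpillar_export(oe_tab),
                   file.path(out_dir, "caterpillar.csv"), row.names = FALSE)

  manifest <- list(
    seeds = list(cohort = config[["cohort"]]$seed, bootstrap = bcfg$seed),
    filter = fcfg,
    bootstrap = list(B = bcfg$B, level = bcfg$level, refit = bcfg$refit,
                     B_effective = boot$B_effective),
    counts = filtered$report,
    n_train = nrow(splits$train), n_validation = nrow(splits$validation),
    category_counts = as.list(categorize_counts(oe_tab$category))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(records = filtered$records, splits = splits, fit = fit,
                 full_fit = full_fit, validation = vtab,
                 hospital_oe = oe_tab, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
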