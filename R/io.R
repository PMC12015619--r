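#' Write / read the cohort CSV
#'
#' One row per admission, one column per record field, header included,
#' missing values as empty cells. The round trip is lossless for the types
#' the generator produces (integers, reals, code strings).
#'
#' @param records cohort data.frame.
#' @param path file path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns the cohort data.frame.
#' @export
write_cohort_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = "", colClasses = NA)
  character_fields <- c("patient_id", "hospital_id", "fiscal_year", "icd10")
  for (f in intersect(character_fields, names(rec)))
    rec[[f]] <- as.character(rec[[f]])
  rec
}
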