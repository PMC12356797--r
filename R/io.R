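cohort_columns <- c("case_id", "true_status", "ai_score", "ct_compatible",
                    "dlco_available", "ref_verdict_1", "ref_verdict_2",
                    "ref_verdict_3", "index_verdict_1", "index_verdict_2")

binary_cohort_columns <- c("true_status", "ct_compatible", "dlco_available",
                           "ref_verdict_1", "ref_verdict_2", "ref_verdict_3",
                           "index_verdict_1", "index_verdict_2")

#' Read an applicant cohort from CSV
#'
#' Reads and validates the cohort schema: one row per applicant with columns
#' `case_id`, `true_status`, `ai_score`, `ct_compatible`, `dlco_available`,
#' `ref_verdict_1..3`, `index_verdict_1..2`. Empty cells are missing values
#' (e.g. no index verdicts for auto-triaged cases, no latent truth for real
#' data). Verdict and flag columns must be 0/1; AI scores must lie in
#' `[0, 100]`. Violations are reported with the offending row and column.
#'
#' @param path Path to a CSV file (comma-separated, UTF-8, `.` decimal).
#' @param strict If `TRUE` (default), columns outside the schema are an
#'   error; otherwise they are carried through untouched.
#' @return A cohort data.frame.
#' @export
read_cohort <- function(path, strict = TRUE) {
  if (!file.exists(path)) stopf("cohort file not found: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(cohort_columns, names(d))
  if (length(missing_cols)) {
    stopf("cohort file %s lacks required column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(d), cohort_columns)
  if (strict && length(extra)) {
    stopf("cohort file %s has unknown column(s) in strict mode: %s", path,
          paste(extra, collapse = ", "))
  }
  validate_cohort(d, context = path)
  d
}

validate_cohort <- function(d, context = "cohort") {
  for (col in intersect(binary_cohort_columns, names(d))) {
    v <- d[[col]]
    bad <- which(!is.na(v) & !(v %in% c(0, 1)))
    if (length(bad)) {
      stopf("%s: column `%s`, row %d: value %s is not a binary 0/1 verdict",
            context, col, bad[1], format(v[bad[1]]))
    }
  }
  bad <- which(!is.na(d$ai_score) & (d$ai_score < 0 | d$ai_score > 100))
  if (length(bad)) {
    stopf("%s: column `ai_score`, row %d: value %s outside [0, 100]",
          context, bad[1], format(d$ai_score[bad[1]]))
  }
  if (anyDuplicated(d$case_id)) stopf("%s: duplicated case_id values", context)
  invisible(d)
}

#' Write an applicant cohort to CSV
#'
#' Inverse of [read_cohort()]: missing values become empty cells, so a
#' write-read round trip preserves all fields.
#'
#' @param cohort Cohort data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write a simulation configuration as YAML
#'
#' The YAML file mirrors the [sim_config()] field names.
#'
#' @param path YAML file path.
#' @return For `read_sim_config`, a validated [sim_config()] object.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown)) {
    stopf("unknown configuration field(s): %s", paste(unknown, collapse = ", "))
  }
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @param config A [sim_config()] object.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' Write a pipeline report as JSON
#'
#' Serialises a [run_pipeline()] report to JSON. Every stochastic result in
#' the report carries the seed that produced it.
#'
#' @param report A `run_report` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  jsonlite::write_json(unclass_deep(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null",
                       na = "null")
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, unclass_deep)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' Validate the structure of a pipeline report
#'
#' Checks a report (or a parsed report JSON) against the shipped report
#' schema (`system.file("schema", "run_report.json", package = "triagedx")`):
#' required stages, required fields per stage, and the rule that every
#' stochastic result carries its seed.
#'
#' @param report A `run_report` object or a list parsed from report JSON.
#' @return `TRUE` invisibly; violations are errors.
#' @export
validate_report <- function(report) {
  schema_path <- system.file("schema", "run_report.json", package = "triagedx")
  schema <- jsonlite::read_json(schema_path)
  rep <- if (inherits(report, "run_report")) unclass_deep(report) else report
  for (stage in names(schema$required_stages)) {
    if (is.null(rep[[stage]])) stopf("report lacks stage `%s`", stage)
    for (fld in unlist(schema$required_stages[[stage]])) {
      if (is.null(rep[[stage]][[fld]])) {
        stopf("report stage `%s` lacks field `%s`", stage, fld)
      }
    }
  }
  for (fld in unlist(schema$required_top_level)) {
    if (is.null(rep[[fld]])) stopf("report lacks top-level field `%s`", fld)
  }
  invisible(TRUE)
}
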