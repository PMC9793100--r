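#' Write a cohort table as CSV with a sidecar JSON schema
#'
#' The schema records each column's role (`psf`, `outcome_binary`,
#' `outcome_numeric`, `meta`) and, where known, the APO/risk-factor class of
#' the outcome columns.
#'
#' @param cohort a `cohort_table`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "cohort.csv")
  schema <- file.path(dir, "cohort.schema.json")
  utils::write.csv(as.data.frame(cohort), csv, row.names = FALSE)
  jsonlite::write_json(
    list(
      roles = as.list(attr(cohort, "roles")),
      outcome_class = as.list(attr(cohort, "outcome_class"))
    ),
    schema,
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(c(csv, schema))
}

#' Read a cohort table written by [write_cohort()]
#'
#' @param dir directory holding `cohort.csv` and `cohort.schema.json`.
#' @return a `cohort_table`.
#' @export
read_cohort <- function(dir) {
  cohort <- utils::read.csv(file.path(dir, "cohort.csv"),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  schema <- jsonlite::read_json(file.path(dir, "cohort.schema.json"))
  attr(cohort, "roles") <- unlist(schema$roles)
  attr(cohort, "outcome_class") <- unlist(schema$outcome_class)
  class(cohort) <- c("cohort_table", "data.frame")
  cohort
}

#' Write an immune panel as CSV plus planted truth as JSON
#'
#' @param panel an `immune_panel`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_immune_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "immune_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "immune_panel.csv")
  truth <- file.path(dir, "immune_truth.json")
  utils::write.csv(
    data.frame(
      patient_id = panel$patient_id, timepoint = panel$timepoint,
      panel$values, check.names = FALSE
    ),
    csv,
    row.names = FALSE
  )
  jsonlite::write_json(
    list(
      signal_features = panel$truth$signal_features,
      beta = apply(panel$truth$beta, 2, identity, simplify = FALSE),
      timepoint_effect = panel$truth$timepoint_effect,
      patients = panel$truth$patients
    ),
    truth,
    auto_unbox = TRUE, digits = NA
  )
  invisible(c(csv, truth))
}

#' Write a feature matrix as CSV plus scaling parameters as JSON
#'
#' @param fm a `feature_matrix`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_feature_matrix <- function(fm, dir) {
  stopifnot(inherits(fm, "feature_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "features.csv")
  utils::write.csv(
    data.frame(patient_id = fm$patient_id, fm$values, check.names = FALSE),
    csv,
    row.names = FALSE
  )
  paths <- csv
  if (!is.null(fm$scaling)) {
    sj <- file.path(dir, "scaling.json")
    jsonlite::write_json(
      fm$scaling[c("feature", "center", "sd", "centered")],
      sj,
      auto_unbox = TRUE, digits = NA
    )
    paths <- c(csv, sj)
  }
  invisible(paths)
}
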