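#' Exclude patients without preeclampsia information
#'
#' Removes every patient whose preeclampsia fields are all missing from both
#' the raw questionnaire and the outcome table, keeping the two aligned on
#' `patient_id`. The removed count is reported via `message()`.
#'
#' @param raw raw questionnaire `data.frame` with a `patient_id` column.
#' @param outcomes outcome `data.frame` with `patient_id` and the
#'   preeclampsia columns.
#' @param pree_cols names of the preeclampsia status columns.
#' @return list with the filtered, aligned `questionnaire` and `outcomes`.
#' @export
exclude_patients <- function(raw, outcomes,
                             pree_cols = c(
                               "severe_preeclampsia",
                               "superimposed_preeclampsia"
                             )) {
  stopifnot("patient_id" %in% names(raw), "patient_id" %in% names(outcomes))
  idx <- match(raw$patient_id, outcomes$patient_id)
  if (anyNA(idx)) {
    stop(
      "alignment error: ", sum(is.na(idx)),
      " questionnaire patients missing from the outcome table"
    )
  }
  outcomes <- outcomes[idx, , drop = FALSE]
  pree_cols <- intersect(pree_cols, names(outcomes))
  if (!length(pree_cols)) {
    stop("no preeclampsia columns found in the outcome table")
  }
  pree <- as.matrix(outcomes[, pree_cols, drop = FALSE])
  drop <- rowSums(!is.na(pree)) == 0
  message(
    "Removed ", sum(drop), " of ", nrow(raw),
    " patients without preeclampsia information; ",
    sum(!drop), " retained."
  )
  if (all(drop)) {
    warning("all patients lack preeclampsia information; empty cohort returned")
  }
  keep <- !drop
  att <- attributes(outcomes)
  out <- outcomes[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in setdiff(names(att), c("names", "row.names", "class"))) {
    attr(out, a) <- att[[a]]
  }
  q <- raw[keep, , drop = FALSE]
  rownames(q) <- NULL
  list(questionnaire = q, outcomes = out)
}

#' Parse configured text columns to numbers
#'
#' Converts configured free-text columns to numeric. The built-in rule parses
#' "preferred bedtime" clock times to minutes after noon on a 24-hour wrap,
#' so "10:30 PM" becomes 630, "noon" 0 and "midnight" 720. Cells that cannot
#' be parsed degrade to missing; text columns not listed are left untouched
#' (they are dropped later by [filter_features()]).
#'
#' @param raw raw questionnaire `data.frame`.
#' @param time_columns character names of clock-time text columns.
#' @return the table with the configured columns replaced by numeric vectors.
#' @export
parse_text_features <- function(raw, time_columns = "preferred_bedtime") {
  for (cl in intersect(time_columns, names(raw))) {
    raw[[cl]] <- parse_clock_time(raw[[cl]])
  }
  raw
}

#' Clock-time text to minutes after noon
#'
#' @param x character vector of clock times ("10:30 PM", "22:30", "noon",
#'   "midnight").
#' @return numeric minutes after noon in `[0, 1440)`; unparseable cells `NA`.
#' @export
parse_clock_time <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_real_, length(x))
  out[x == "noon"] <- 0
  out[x == "midnight"] <- 720
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})\\s*(am|pm)?$", x))
  for (i in seq_along(m)) {
    if (length(m[[i]]) == 0) next
    h <- as.integer(m[[i]][2])
    mi <- as.integer(m[[i]][3])
    ap <- m[[i]][4]
    if (mi > 59) next
    if (nzchar(ap)) {
      if (h < 1 || h > 12) next
      h <- h %% 12 + if (ap == "pm") 12 else 0
    } else if (h > 23) {
      next
    }
    out[i] <- ((h * 60 + mi) - 720) %% 1440
  }
  out
}

#' Filter questionnaire columns down to the predictor matrix
#'
#' Applies the documented filter chain in order: (1) drop all non-numeric
#' columns, (2) drop columns with at most one unique non-missing value
#' (which covers constant and all-missing columns), (3) drop named
#' age-inapplicable items (by default the "life stress 41-50" question,
#' inapplicable because the whole cohort is younger than 41).
#'
#' @param raw raw questionnaire `data.frame`, text parsing already applied.
#' @param drop_items character names of items to drop regardless of content.
#' @param id_col name of the patient identifier column.
#' @return a `feature_matrix`: list with `values` (patients x features
#'   numeric matrix, missing entries allowed), `patient_id`, `feature_names`
#'   and `scaling` (`NULL` until [scale_features()]).
#' @export
filter_features <- function(raw, drop_items = "life_stress_41_50",
                            id_col = "patient_id") {
  stopifnot(id_col %in% names(raw))
  cols <- setdiff(names(raw), id_col)
  numeric_cols <- cols[vapply(raw[cols], is.numeric, TRUE)]
  n_unique <- vapply(
    raw[numeric_cols],
    function(v) length(unique(v[!is.na(v)])),
    0L
  )
  keep <- numeric_cols[n_unique > 1L]
  keep <- setdiff(keep, drop_items)
  if (!length(keep)) {
    stop("no predictors retained")
  }
  values <- as.matrix(raw[, keep, drop = FALSE])
  storage.mode(values) <- "double"
  structure(
    list(
      values = values,
      patient_id = raw[[id_col]],
      feature_names = keep,
      scaling = NULL
    ),
    class = "feature_matrix"
  )
}

#' Scale predictor columns to unit variance
#'
#' Divides each column by its sample standard deviation (n - 1 convention)
#' computed on the non-missing entries of the fitting rows only, optionally
#' mean-centering first (the default; disable with `center = FALSE`).
#' Missing entries are then imputed with the fitting-split mean (0 after
#' centering). The location/scale used are stored in `$scaling` and can be
#' replayed on held-out data with [apply_scaling()], so no information leaks
#' from evaluation rows into the scaling.
#'
#' @param fm a `feature_matrix` from [filter_features()].
#' @param fit integer rows defining the fitting split (default: all rows).
#' @param center also mean-center the columns.
#' @return the `feature_matrix` with scaled, imputed `values` and populated
#'   `scaling`.
#' @export
scale_features <- function(fm, fit = seq_len(nrow(fm$values)), center = TRUE) {
  stopifnot(inherits(fm, "feature_matrix"))
  X <- fm$values
  sds <- apply(X[fit, , drop = FALSE], 2, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sds) | sds == 0)) {
    bad <- fm$feature_names[!is.finite(sds) | sds == 0]
    stop(
      "zero-variance column(s) at scaling time (should have been filtered): ",
      paste(bad, collapse = ", ")
    )
  }
  ctr <- apply(X[fit, , drop = FALSE], 2, mean, na.rm = TRUE)
  scaling <- list(
    feature = fm$feature_names, center = ctr, sd = sds,
    centered = center, fit_rows = fit
  )
  fm$values <- apply_scaling_matrix(X, scaling)
  fm$scaling <- scaling
  fm
}

apply_scaling_matrix <- function(X, scaling) {
  Z <- sweep(X, 2, if (scaling$centered) scaling$center else 0, "-")
  Z <- sweep(Z, 2, scaling$sd, "/")
  imputed <- if (scaling$centered) {
    rep(0, ncol(X))
  } else {
    scaling$center / scaling$sd
  }
  for (j in seq_len(ncol(Z))) {
    Z[is.na(Z[, j]), j] <- imputed[j]
  }
  Z
}

#' Apply stored scaling parameters to held-out data
#'
#' @param fm a `feature_matrix` with raw values (columns must match the
#'   features the parameters were fit on).
#' @param scaling the `$scaling` element of a fitted [scale_features()]
#'   result.
#' @return the `feature_matrix` scaled and imputed with the stored
#'   parameters.
#' @export
apply_scaling <- function(fm, scaling) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!identical(fm$feature_names, scaling$feature)) {
    stop("feature names do not match the stored scaling parameters")
  }
  fm$values <- apply_scaling_matrix(fm$values, scaling)
  fm$scaling <- scaling
  fm
}
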