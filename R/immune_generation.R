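#' Collapse a ridge ensemble into one linear generator
#'
#' Takes the element-wise arithmetic mean of the fitted coefficients and
#' intercepts over every repetition x fold slice of the ensemble, together
#' with the fold-averaged stressor scaling parameters, yielding a single
#' linear model that maps (scaled) stressors plus timepoint to immune
#' features.
#'
#' @param ens a `ridge_ensemble` from [grouped_repeated_cv()].
#' @return object of class `linear_generator`: list with `W` (immune
#'   features x predictors), `b` (intercepts), `predictor_names`,
#'   `feature_names` and `scaling` (averaged centers and sds for the
#'   stressor columns).
#' @export
average_ensemble <- function(ens) {
  stopifnot(inherits(ens, "ridge_ensemble"), length(ens$slices) >= 1)
  pn <- rownames(ens$slices[[1]]$coef)
  for (s in ens$slices) {
    if (!identical(rownames(s$coef), pn)) {
      stop("inconsistent predictor orderings across ensemble slices")
    }
    if (!all(is.finite(s$coef)) || !all(is.finite(s$intercept))) {
      stop("non-finite coefficients in ensemble slice")
    }
  }
  ns <- length(ens$slices)
  W <- Reduce(`+`, lapply(ens$slices, `[[`, "coef")) / ns
  b <- Reduce(`+`, lapply(ens$slices, `[[`, "intercept")) / ns
  ctr <- Reduce(`+`, lapply(ens$slices, `[[`, "center")) / ns
  sds <- Reduce(`+`, lapply(ens$slices, `[[`, "sd")) / ns
  structure(
    list(
      W = t(W), b = b,
      predictor_names = pn,
      feature_names = ens$feature_names,
      scaling = list(center = ctr, sd = sds)
    ),
    class = "linear_generator"
  )
}

#' Generate in-silico immune features from stressors
#'
#' Applies the averaged linear model to a stressor matrix: stressor columns
#' are scaled with the generator's stored fold-averaged parameters (missing
#' entries imputed at the training mean), the requested timepoint code is
#' appended, and the exact affine map `X W' + b` is evaluated. No noise is
#' injected; repeated calls are bitwise identical.
#'
#' @param gen a `linear_generator`.
#' @param features a `feature_matrix` of raw stressors for the patients to
#'   impute (columns must match the generator's stressor predictors).
#' @param timepoint timepoint code 1-4 the generated features represent
#'   (default 1, the first trimester, when stressors were assessed).
#' @return numeric matrix (patients x immune features) with patient IDs as
#'   row names and the timepoint in `attr(, "timepoint")`.
#' @export
generate_features <- function(gen, features, timepoint = 1L) {
  stopifnot(inherits(gen, "linear_generator"))
  stopifnot(length(timepoint) == 1, timepoint %in% 1:4)
  fvals <- if (inherits(features, "feature_matrix")) features$values else as.matrix(features)
  fnames <- if (inherits(features, "feature_matrix")) features$feature_names else colnames(fvals)
  ids <- if (inherits(features, "feature_matrix")) features$patient_id else rownames(fvals)
  psf_pred <- setdiff(gen$predictor_names, "timepoint")
  missing <- setdiff(psf_pred, fnames)
  extra <- setdiff(fnames, psf_pred)
  if (length(missing) || length(extra)) {
    stop(
      "predictor mismatch; missing: [",
      paste(missing, collapse = ", "), "]; extra: [",
      paste(extra, collapse = ", "), "]"
    )
  }
  X <- fvals[, psf_pred, drop = FALSE]
  Z <- sweep(sweep(X, 2, gen$scaling$center), 2, gen$scaling$sd, "/")
  Z[is.na(Z)] <- 0
  Z <- add_timepoint(Z, rep(as.integer(timepoint), nrow(Z)))
  out <- sweep(tcrossprod(Z, gen$W), 2, gen$b, "+")
  colnames(out) <- gen$feature_names
  rownames(out) <- ids
  attr(out, "timepoint") <- as.integer(timepoint)
  out
}

#' Predict APORFs from generated immune features
#'
#' Runs the same multitask vs single-task repeated stratified K-fold
#' comparison with in-silico generated immune features as the input. The
#' patients whose immune features were actually measured must be excluded
#' upstream; passing any of them raises an error, since their measured data
#' trained the generator.
#'
#' @param gen_matrix generated immune feature matrix from
#'   [generate_features()] (row names are patient IDs).
#' @param outcomes `cohort_table` rows aligned with `gen_matrix`.
#' @param cfg a [network_config()] whose `n_features` matches the generated
#'   feature count.
#' @param immune_patients IDs of the immune-measured patients (for the
#'   exclusion check).
#' @param ... passed to [evaluate_repeated_kfold()] (`k`, `n_repetitions`,
#'   `model_classes`, `singletask_tasks`).
#' @param paired use the paired Wilcoxon variant in the comparison table.
#' @return list with `evaluation` (an `mt_evaluation`) and `comparison`
#'   (per-task table with medians, p-values and stars).
#' @export
predict_aporfs_from_generated <- function(gen_matrix, outcomes, cfg,
                                          immune_patients = character(),
                                          paired = TRUE, ...) {
  ids <- rownames(gen_matrix)
  stopifnot(!is.null(ids), nrow(gen_matrix) == nrow(outcomes))
  if (!identical(ids, outcomes$patient_id)) {
    stop("gen_matrix rows and outcomes are not aligned on patient_id")
  }
  overlap <- intersect(ids, immune_patients)
  if (length(overlap)) {
    stop(
      "immune-measured patients must be excluded before prediction: ",
      paste(utils::head(overlap, 5), collapse = ", ")
    )
  }
  eval <- evaluate_repeated_kfold(gen_matrix, outcomes, cfg, ...)
  cmp <- if (all(c("multitask", "singletask") %in% eval$performance$model_class)) {
    comparison_table(eval, paired = paired)
  } else {
    NULL
  }
  list(evaluation = eval, comparison = cmp)
}
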