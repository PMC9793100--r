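#' Configuration of the grouped repeated ridge screen
#'
#' Defaults follow the protocol of the study this pipeline emulates: alpha grid
#' `(1, 0.1, 0.01, 0.001, 0.0001, 0)`, shuffled grouped 10-fold outer
#' cross-validation keeping all four timepoints of a patient in one fold,
#' 50 repetitions, and Benjamini-Hochberg control at 0.05 on the
#' per-feature mean p-values. The inner loop that picks the alpha is not
#' detailed in the protocol; a grouped 5-fold grid search by mean squared
#' error inside each training portion is used.
#'
#' @param alpha_grid non-negative ridge penalties searched (0 means
#'   minimum-norm least squares).
#' @param k_outer outer grouped folds.
#' @param k_inner inner grouped folds for alpha selection.
#' @param n_repetitions repetitions of the shuffled outer split.
#' @param fdr_alpha Benjamini-Hochberg level.
#' @param seed base seed; repetition `r` uses `seed + r`.
#' @return object of class `ridge_config`.
#' @export
ridge_config <- function(alpha_grid = c(1, 0.1, 0.01, 0.001, 0.0001, 0),
                         k_outer = 10, k_inner = 5, n_repetitions = 50,
                         fdr_alpha = 0.05, seed = 1L) {
  stopifnot(
    all(alpha_grid >= 0), k_outer >= 2, k_inner >= 2,
    n_repetitions >= 1, fdr_alpha > 0, fdr_alpha < 1
  )
  structure(
    list(
      alpha_grid = alpha_grid, k_outer = as.integer(k_outer),
      k_inner = as.integer(k_inner),
      n_repetitions = as.integer(n_repetitions),
      fdr_alpha = fdr_alpha, seed = as.integer(seed)
    ),
    class = "ridge_config"
  )
}

# Multi-response ridge via one SVD of the centered design: coefficients for
# every alpha in the grid from a single decomposition. alpha = 0 yields the
# minimum-norm least-squares solution (small singular values truncated).
ridge_solve_grid <- function(X, Y, alphas, intercept = TRUE) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (intercept) {
    xm <- colMeans(X)
    ym <- colMeans(Y)
    Xc <- sweep(X, 2, xm)
    Yc <- sweep(Y, 2, ym)
  } else {
    xm <- numeric(ncol(X))
    ym <- numeric(ncol(Y))
    Xc <- X
    Yc <- Y
  }
  sv <- svd(Xc)
  uty <- crossprod(sv$u, Yc)
  tol <- max(dim(Xc)) * max(sv$d, 0) * .Machine$double.eps
  lapply(alphas, function(a) {
    if (a > 0) {
      shrink <- sv$d / (sv$d^2 + a)
    } else {
      shrink <- ifelse(sv$d > tol, 1 / sv$d, 0)
    }
    B <- sv$v %*% (shrink * uty)
    b0 <- ym - drop(crossprod(B, xm))
    dimnames(B) <- list(colnames(X), colnames(Y))
    list(coef = B, intercept = b0, alpha = a)
  })
}

#' Ridge regression fit (closed form)
#'
#' Minimizes `||y - X b - b0||^2 + alpha * ||b||^2` with an unpenalized
#' intercept (set `intercept = FALSE` for the raw normal-equation form
#' `(X'X + alpha I)^-1 X'y`). `alpha = 0` returns the minimum-norm
#' least-squares solution via the pseudo-inverse, which is the relevant
#' regime here since the stressor design has more predictors than training
#' rows.
#'
#' @param X design matrix (column-scaled upstream).
#' @param y response vector.
#' @param alpha non-negative penalty.
#' @param intercept fit an unpenalized intercept.
#' @return list with `coef` (named vector) and `intercept`.
#' @export
ridge_fit <- function(X, y, alpha, intercept = TRUE) {
  stopifnot(alpha >= 0)
  f <- ridge_solve_grid(X, matrix(y, ncol = 1), alpha, intercept = intercept)[[1]]
  list(coef = drop(f$coef), intercept = unname(f$intercept))
}

#' Append the timepoint code column to a design matrix
#'
#' The timepoint enters the immune models as a sequential integer 1 to 4
#' (first, second, third trimester, postpartum), appended as-is after the
#' stressor columns.
#'
#' @param X design matrix.
#' @param timepoints integer codes in `{1, 2, 3, 4}`, one per row.
#' @return `X` with a final `timepoint` column.
#' @export
add_timepoint <- function(X, timepoints) {
  X <- as.matrix(X)
  if (nrow(X) == 0) {
    return(cbind(X, timepoint = numeric(0)))
  }
  stopifnot(length(timepoints) == nrow(X))
  if (!all(timepoints %in% 1:4)) {
    stop(
      "unknown timepoint code(s): ",
      paste(unique(timepoints[!timepoints %in% 1:4]), collapse = ", ")
    )
  }
  cbind(X, timepoint = as.numeric(timepoints))
}

#' Benjamini-Hochberg step-up correction
#'
#' @param p p-values in `[0, 1]`.
#' @param alpha false discovery rate level.
#' @return list with monotone adjusted values `q` and the `rejected` mask
#'   (`q < alpha`).
#' @export
bh_correct <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, rejected = !is.na(q) & q < alpha)
}

#' Grouped repeated cross-validated ridge screen of immune features
#'
#' For each repetition: shuffle patients into `k_outer` grouped folds (all
#' timepoints of a patient stay together); inside every training portion run
#' a grouped `k_inner`-fold grid search selecting, per immune feature, the
#' alpha with the lowest validation mean squared error; refit on the full
#' training portion and predict the held-out patient-timepoints. Stressor
#' columns are scaled to unit variance (and centered) with training-portion
#' statistics; the timepoint column stays a raw integer. Per repetition,
#' Spearman rho and p are computed per immune feature over all pooled
#' held-out samples; rho and p are averaged over repetitions and the
#' Benjamini-Hochberg correction is applied to the mean p-values. Every
#' fitted coefficient vector is accumulated into a `ridge_ensemble`.
#'
#' @param panel an `immune_panel`.
#' @param features a `feature_matrix` of raw (unscaled) stressors for at
#'   least the panel patients.
#' @param cfg a [ridge_config()].
#' @return list with `predictability` (data frame: immune_feature, mean_rho,
#'   mean_p, q, significant; per-repetition matrices in attributes
#'   `per_repetition_rho` / `per_repetition_p`) and `ensemble` (a
#'   `ridge_ensemble`).
#' @export
grouped_repeated_cv <- function(panel, features, cfg) {
  stopifnot(inherits(panel, "immune_panel"), inherits(cfg, "ridge_config"))
  fvals <- if (inherits(features, "feature_matrix")) features$values else as.matrix(features)
  fids <- if (inherits(features, "feature_matrix")) features$patient_id else rownames(features)
  idx <- match(panel$patient_id, fids)
  if (anyNA(idx)) {
    stop("panel patients missing from the feature matrix")
  }
  if (length(unique(panel$patient_id)) < cfg$k_outer) {
    stop("fewer patients than outer folds")
  }
  Xp <- fvals[idx, , drop = FALSE] # one row per panel row (patient-expanded)
  Y <- panel$values
  m <- ncol(Y)
  n <- nrow(Y)
  alphas <- sort(cfg$alpha_grid, decreasing = TRUE)

  slices <- list()
  rho_rep <- matrix(NA_real_, cfg$n_repetitions, m)
  p_rep <- matrix(NA_real_, cfg$n_repetitions, m)
  for (r in seq_len(cfg$n_repetitions)) {
    set.seed(cfg$seed + r)
    folds <- grouped_folds(panel$patient_id, cfg$k_outer)
    pred <- matrix(NA_real_, n, m)
    for (f in seq_along(folds)) {
      test <- folds[[f]]
      train <- setdiff(seq_len(n), test)
      sc <- standardize_by_fit(Xp, fit = train)
      Xs <- add_timepoint(sc$values, panel$timepoint)
      Xtr <- Xs[train, , drop = FALSE]
      Ytr <- Y[train, , drop = FALSE]

      best_alpha <- select_alpha_grouped(
        Xtr, Ytr, panel$patient_id[train], alphas, cfg$k_inner
      )
      fits <- ridge_solve_grid(Xtr, Ytr, alphas)
      coef_fold <- matrix(0, ncol(Xs), m, dimnames = list(colnames(Xs), colnames(Y)))
      int_fold <- numeric(m)
      for (ai in seq_along(alphas)) {
        cols <- which(best_alpha == ai)
        if (!length(cols)) next
        coef_fold[, cols] <- fits[[ai]]$coef[, cols]
        int_fold[cols] <- fits[[ai]]$intercept[cols]
      }
      pred[test, ] <- sweep(
        Xs[test, , drop = FALSE] %*% coef_fold, 2, int_fold, "+"
      )
      slices[[length(slices) + 1]] <- list(
        repetition = r, fold = f,
        coef = coef_fold, intercept = int_fold,
        center = sc$center, sd = sc$sd,
        alpha = alphas[best_alpha],
        test_patients = unique(panel$patient_id[test])
      )
    }
    cs <- col_spearman(pred, Y)
    rho_rep[r, ] <- cs$rho
    p_rep[r, ] <- cs$p
  }
  mean_rho <- colMeans(rho_rep)
  mean_p <- colMeans(p_rep)
  bh <- bh_correct(mean_p, cfg$fdr_alpha)
  predictability <- data.frame(
    immune_feature = panel$feature_names,
    mean_rho = mean_rho,
    mean_p = mean_p,
    q = bh$q,
    significant = bh$rejected,
    stringsAsFactors = FALSE
  )
  attr(predictability, "per_repetition_rho") <- rho_rep
  attr(predictability, "per_repetition_p") <- p_rep
  ensemble <- structure(
    list(
      slices = slices,
      predictor_names = c(
        if (inherits(features, "feature_matrix")) features$feature_names else colnames(fvals),
        "timepoint"
      ),
      feature_names = panel$feature_names,
      cfg = cfg
    ),
    class = "ridge_ensemble"
  )
  list(predictability = predictability, ensemble = ensemble)
}

# Per-feature alpha index with the lowest grouped inner-CV SSE. Operates
# strictly inside the supplied (training) rows. Ties resolve toward the
# stronger penalty (alphas are passed sorted decreasing).
select_alpha_grouped <- function(Xtr, Ytr, groups, alphas, k_inner) {
  k <- min(k_inner, length(unique(groups)))
  if (k < 2) {
    stop("inner alpha selection needs at least two patient groups")
  }
  inner <- grouped_folds(groups, k)
  sse <- matrix(0, length(alphas), ncol(Ytr))
  for (fi in seq_along(inner)) {
    val <- inner[[fi]]
    fit_rows <- setdiff(seq_len(nrow(Xtr)), val)
    fits <- ridge_solve_grid(
      Xtr[fit_rows, , drop = FALSE], Ytr[fit_rows, , drop = FALSE], alphas
    )
    for (ai in seq_along(alphas)) {
      pv <- sweep(
        Xtr[val, , drop = FALSE] %*% fits[[ai]]$coef, 2,
        fits[[ai]]$intercept, "+"
      )
      sse[ai, ] <- sse[ai, ] + colSums((pv - Ytr[val, , drop = FALSE])^2)
    }
  }
  apply(sse, 2, which.min)
}

#' Write the immune predictability table as CSV
#'
#' @param predictability the `predictability` element of
#'   [grouped_repeated_cv()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_predictability <- function(predictability, path) {
  utils::write.csv(predictability, path, row.names = FALSE)
  invisible(path)
}
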