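#' Spearman rank correlation with pairwise-complete deletion
#'
#' Rank correlation with average ranks for ties and a two-sided p-value from
#' the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of
#' freedom. Entries where either vector is missing are dropped pairwise.
#' Fewer than three complete pairs (or a zero-variance margin) yields an
#' undefined-result marker (`NA`) rather than an error, so correlation
#' matrices over sparse questionnaire items degrade gracefully.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with elements `rho`, `p` and `n` (complete pairs used).
#' @examples
#' spearman_cor(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))$rho  # 0.8
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3L) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rx <- rank(x[ok])
  ry <- rank(y[ok])
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rx, ry)
  rho <- max(-1, min(1, rho))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

# Column-wise Spearman rho/p between matched columns of two complete matrices.
# Used on pooled cross-validation predictions where no values are missing.
col_spearman <- function(pred, truth) {
  stopifnot(identical(dim(pred), dim(truth)))
  n <- nrow(pred)
  rp <- apply(pred, 2, rank)
  rt <- apply(truth, 2, rank)
  rp <- scale(rp)
  rt <- scale(rt)
  rho <- colSums(rp * rt) / (n - 1)
  rho[!is.finite(rho)] <- NA_real_
  rho <- pmax(-1, pmin(1, rho))
  p <- rep(NA_real_, length(rho))
  defined <- !is.na(rho)
  r <- rho[defined]
  p[defined] <- ifelse(
    abs(r) >= 1, 0,
    2 * stats::pt(-abs(r * sqrt((n - 2) / (1 - r^2))), df = n - 2)
  )
  list(rho = as.numeric(rho), p = as.numeric(p))
}

#' Area under the ROC curve
#'
#' Computed through the rank (Mann-Whitney) identity
#' `AUROC = (sum of positive ranks - n1(n1+1)/2) / (n1 * n0)`, which equals
#' the fraction of concordant positive/negative score pairs with ties
#' credited one half.
#'
#' @param y binary truth (0/1 or logical).
#' @param score numeric scores, larger meaning more positive.
#' @return AUROC in `[0, 1]`, or `NA` if only one class is present.
#' @export
auroc <- function(y, score) {
  y <- as.integer(y > 0)
  stopifnot(length(y) == length(score))
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) {
    return(NA_real_)
  }
  r <- rank(score)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Significance star label
#'
#' Maps a p-value to the conventional star annotation used in the model
#' comparison figures: `ns` for p > 0.05, then `*`, `**`, `***`, `****` at
#' 0.05, 0.01, 0.001 and 0.0001.
#'
#' @param p p-value in `[0, 1]`.
#' @return character label.
#' @export
star_label <- function(p) {
  stopifnot(is.numeric(p), length(p) == 1L)
  if (is.na(p)) {
    return(NA_character_)
  }
  if (p <= 1e-4) "****" else if (p <= 1e-3) "***" else if (p <= 0.01) "**" else if (p <= 0.05) "*" else "ns"
}

# Shuffled grouped K-fold: every row of one group lands in exactly one fold.
# Returns a list of k test-row index vectors covering seq_along(groups).
grouped_folds <- function(groups, k) {
  ug <- unique(groups)
  if (length(ug) < k) {
    stop("fewer groups (", length(ug), ") than folds (", k, ")")
  }
  ug <- sample(ug)
  fold_of_group <- rep(seq_len(k), length.out = length(ug))
  lapply(seq_len(k), function(f) {
    which(groups %in% ug[fold_of_group == f])
  })
}

# Stratified K-fold test indices (delegates to caret).
stratified_folds <- function(label, k) {
  caret::createFolds(factor(label), k = k, list = TRUE, returnTrain = FALSE)
}

# Standardize columns of a (possibly incomplete) matrix using statistics from
# `fit` rows only; missing entries become the fit mean (0 after centering).
# Zero-variance columns get sd 1 so they map to a constant instead of NaN.
standardize_by_fit <- function(X, fit = seq_len(nrow(X)), center = TRUE) {
  ctr <- apply(X[fit, , drop = FALSE], 2, mean, na.rm = TRUE)
  sds <- apply(X[fit, , drop = FALSE], 2, stats::sd, na.rm = TRUE)
  sds[!is.finite(sds) | sds == 0] <- 1
  ctr[!is.finite(ctr)] <- 0
  Z <- sweep(X, 2, if (center) ctr else 0, "-")
  Z <- sweep(Z, 2, sds, "/")
  imputed <- if (center) rep(0, ncol(X)) else ctr / sds
  for (j in seq_len(ncol(Z))) {
    Z[is.na(Z[, j]), j] <- imputed[j]
  }
  list(values = Z, center = ctr, sd = sds)
}
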