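#' Default latent correlation matrix for the seven modelled APORFs
#'
#' A positive semi-definite correlation matrix over the latent liabilities of
#' the seven modelled outcomes: hypertension, diabetes, gestational diabetes,
#' superimposed preeclampsia, severe preeclampsia, gestational age at
#' delivery and pre-pregnancy BMI. The default encodes the qualitative
#' structure of the outcome network: a tightly connected
#' hypertensive/metabolic cluster (hypertension, diabetes, superimposed and
#' severe preeclampsia), BMI moderately tied to that cluster, and gestational
#' age at delivery most related to the preeclampsias and gestational
#' diabetes. Binary labels thresholded from these liabilities attenuate the
#' correlations substantially at the configured prevalences, so the latent
#' values are deliberately high.
#'
#' @return 7 x 7 named correlation matrix.
#' @export
default_outcome_corr <- function() {
  nm <- aporf_names()
  R <- diag(7)
  dimnames(R) <- list(nm, nm)
  set2 <- function(a, b, v) {
    R[a, b] <<- v
    R[b, a] <<- v
  }
  set2("hypertension", "diabetes", 0.80)
  set2("hypertension", "superimposed_preeclampsia", 0.80)
  set2("hypertension", "severe_preeclampsia", 0.75)
  set2("diabetes", "superimposed_preeclampsia", 0.75)
  set2("diabetes", "severe_preeclampsia", 0.75)
  set2("superimposed_preeclampsia", "severe_preeclampsia", 0.80)
  set2("gestational_diabetes", "hypertension", 0.50)
  set2("gestational_diabetes", "diabetes", 0.55)
  set2("gestational_diabetes", "superimposed_preeclampsia", 0.45)
  set2("gestational_diabetes", "severe_preeclampsia", 0.45)
  set2("gestational_diabetes", "ga_delivery", 0.55)
  set2("gestational_diabetes", "bmi", 0.50)
  set2("ga_delivery", "hypertension", 0.45)
  set2("ga_delivery", "diabetes", 0.45)
  set2("ga_delivery", "superimposed_preeclampsia", 0.60)
  set2("ga_delivery", "severe_preeclampsia", 0.60)
  set2("ga_delivery", "bmi", 0.50)
  set2("bmi", "hypertension", 0.60)
  set2("bmi", "diabetes", 0.60)
  set2("bmi", "superimposed_preeclampsia", 0.55)
  set2("bmi", "severe_preeclampsia", 0.55)
  make_psd(R)
}

aporf_names <- function() {
  c(
    "hypertension", "diabetes", "gestational_diabetes",
    "superimposed_preeclampsia", "severe_preeclampsia",
    "ga_delivery", "bmi"
  )
}

# Project a symmetric matrix onto the PSD cone (eigenvalue floor) and
# renormalize to unit diagonal.
make_psd <- function(R, floor = 1e-6) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= floor) {
    return(R)
  }
  v <- pmax(e$values, floor)
  R2 <- e$vectors %*% diag(v) %*% t(e$vectors)
  d <- 1 / sqrt(diag(R2))
  R2 <- R2 * tcrossprod(d)
  dimnames(R2) <- dimnames(R)
  (R2 + t(R2)) / 2
}

#' Default PSF-to-liability effect loadings
#'
#' Builds a `sum(block_sizes)` x 7 loading matrix giving every stressor in a
#' handful of "causal" blocks a shared loading on selected outcome
#' liabilities. Block 1 plays the role of life stress (severe preeclampsia,
#' gestational age at delivery), block 2 of metabolic/health stress
#' (diabetes, BMI, gestational diabetes, hypertension), block 3 of perceived
#' pregnancy risks (hypertension, superimposed and severe preeclampsia) and
#' block 4 of sleep/fatigue (gestational age, BMI). Columns are rescaled at
#' generation time so each nonzero outcome receives a PSF-driven liability
#' variance share of `effect_share`, a moderate effect size typical of
#' psychosocial predictors of clinical outcomes.
#'
#' @param block_sizes integer vector of PSF block sizes.
#' @return matrix of loadings (PSFs x 7 outcomes), zero rows for non-causal
#'   blocks.
#' @export
default_psf_effects <- function(block_sizes = default_psf_blocks()) {
  p <- sum(block_sizes)
  block <- rep(seq_along(block_sizes), block_sizes)
  B <- matrix(0, p, 7, dimnames = list(NULL, aporf_names()))
  bw <- list(
    `1` = c(severe_preeclampsia = 1, ga_delivery = 1, gestational_diabetes = 0.5),
    `2` = c(diabetes = 1, bmi = 1, gestational_diabetes = 0.8, hypertension = 0.6),
    `3` = c(hypertension = 1, superimposed_preeclampsia = 1, severe_preeclampsia = 0.6),
    `4` = c(ga_delivery = 0.7, bmi = 0.5)
  )
  for (bl in names(bw)) {
    rows <- block == as.integer(bl)
    w <- bw[[bl]]
    B[rows, names(w)] <- matrix(w, sum(rows), length(w), byrow = TRUE)
  }
  B
}

#' Default PSF block sizes
#'
#' Fifteen correlated blocks summing to the 79 retained stressors, mirroring
#' the fifteen stressor categories that emerge from the correlation-profile
#' clustering.
#'
#' @return integer vector of length 15 summing to 79.
#' @export
default_psf_blocks <- function() {
  c(6, 6, 6, 6, rep(5, 11))
}

#' Specification of a synthetic cohort
#'
#' Collects every knob of the synthetic-cohort generator and validates the
#' feasibility constraints. Defaults reproduce the study composition: 200
#' patients; 18 hypertension, 11 diabetes, 29 gestational diabetes, 6
#' superimposed preeclampsia, 13 severe preeclampsia and 17 preterm cases; 52
#' patients with at least one APORF; 79 stressors in 15 correlated blocks; a
#' gestational age at questionnaire completion with median 11 weeks.
#'
#' @param n_patients cohort size.
#' @param outcome_case_counts named counts for the six binary outcome labels
#'   (`preterm_birth` is derived from the gestational-age liability).
#' @param n_any_aporf number of distinct patients with at least one positive
#'   label.
#' @param outcome_latent_corr 7 x 7 PSD latent correlation matrix, see
#'   [default_outcome_corr()].
#' @param psf_block_sizes sizes of the correlated stressor blocks.
#' @param psf_block_corr within-block latent correlation in `[0, 1)`.
#' @param psf_effect_matrix PSF x outcome liability loadings, see
#'   [default_psf_effects()]; a zero matrix severs the PSF-outcome link.
#' @param effect_share fraction of liability variance carried by the PSF
#'   component for outcomes with nonzero loadings.
#' @param ga_questionnaire_median_weeks median gestational age (weeks) at
#'   questionnaire completion.
#' @param missing_rate completely-at-random missingness applied to observed
#'   PSF entries.
#' @param seed integer seed; generation is fully deterministic given the spec.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 200,
                        outcome_case_counts = c(
                          hypertension = 18, diabetes = 11,
                          gestational_diabetes = 29,
                          superimposed_preeclampsia = 6,
                          severe_preeclampsia = 13,
                          preterm_birth = 17
                        ),
                        n_any_aporf = 52,
                        outcome_latent_corr = default_outcome_corr(),
                        psf_block_sizes = default_psf_blocks(),
                        psf_block_corr = 0.6,
                        psf_effect_matrix = default_psf_effects(psf_block_sizes),
                        effect_share = 0.3,
                        ga_questionnaire_median_weeks = 11,
                        missing_rate = 0.05,
                        seed = 1L) {
  counts <- outcome_case_counts
  need <- c(
    "hypertension", "diabetes", "gestational_diabetes",
    "superimposed_preeclampsia", "severe_preeclampsia", "preterm_birth"
  )
  if (!all(need %in% names(counts))) {
    stop("outcome_case_counts must name: ", paste(need, collapse = ", "))
  }
  counts <- counts[need]
  if (any(counts < 0) || any(counts > n_patients)) {
    stop("each case count must lie in [0, n_patients]")
  }
  lo <- max(counts)
  hi <- min(n_patients, sum(counts))
  if (n_any_aporf < lo || n_any_aporf > hi) {
    stop(
      "infeasible n_any_aporf = ", n_any_aporf,
      ": must lie in [max(case counts) = ", lo,
      ", min(n_patients, sum(case counts)) = ", hi, "]"
    )
  }
  stopifnot(
    isSymmetric(outcome_latent_corr),
    all(abs(outcome_latent_corr) <= 1 + 1e-12),
    all(abs(diag(outcome_latent_corr) - 1) < 1e-8),
    psf_block_corr >= 0, psf_block_corr < 1,
    nrow(psf_effect_matrix) == sum(psf_block_sizes),
    ncol(psf_effect_matrix) == 7,
    effect_share >= 0, effect_share < 1,
    missing_rate >= 0, missing_rate < 1
  )
  ev <- eigen(outcome_latent_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("outcome_latent_corr is not positive semi-definite")
  }
  structure(
    list(
      n_patients = n_patients,
      outcome_case_counts = counts,
      n_any_aporf = n_any_aporf,
      outcome_latent_corr = outcome_latent_corr,
      psf_block_sizes = psf_block_sizes,
      psf_block_corr = psf_block_corr,
      psf_effect_matrix = psf_effect_matrix,
      effect_share = effect_share,
      ga_questionnaire_median_weeks = ga_questionnaire_median_weeks,
      missing_rate = missing_rate,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Generate a synthetic cohort table
#'
#' Draws block-correlated latent stressors, forms outcome liabilities as a
#' mixture of a PSF-driven component and a correlated multivariate-Gaussian
#' residual, thresholds liabilities at the empirical quantile matching each
#' configured case count, and repairs the union of positives by minimal label
#' swaps until exactly `n_any_aporf` patients carry at least one label.
#' Gestational age at delivery is an exact monotone (piecewise-linear) map of
#' its liability calibrated so the preterm (< 37 weeks) count is exact;
#' pre-pregnancy BMI is linear in its liability. Observed stressor columns
#' are partial discretizations of the latent Gaussians (8-point ordinal,
#' yes/no binary, continuous score) with completely-at-random missingness.
#'
#' @param spec a [cohort_spec()].
#' @return a `cohort_table`: a `data.frame` with `patient_id`, outcome
#'   columns, `ga_questionnaire_weeks` and PSF columns. Column roles are in
#'   `attr(, "roles")`; APO-vs-risk-factor classes in
#'   `attr(, "outcome_class")`; the planted truth (loadings, liabilities,
#'   block labels) in `attr(, "planted")`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  sizes <- spec$psf_block_sizes
  p <- sum(sizes)
  block <- rep(seq_along(sizes), sizes)

  # latent stressors: one shared factor per block plus idiosyncratic noise
  r <- spec$psf_block_corr
  f <- matrix(stats::rnorm(n * length(sizes)), n)
  Zl <- sqrt(r) * f[, block, drop = FALSE] +
    sqrt(1 - r) * matrix(stats::rnorm(n * p), n)

  # liabilities: PSF-driven share + correlated residual, standardized
  B <- spec$psf_effect_matrix
  eta <- Zl %*% B
  Cch <- chol(make_psd(spec$outcome_latent_corr))
  eps <- matrix(stats::rnorm(n * 7), n) %*% Cch
  liab <- matrix(0, n, 7, dimnames = list(NULL, aporf_names()))
  for (j in seq_len(7)) {
    ej <- eta[, j]
    if (stats::sd(ej) > 0 && spec$effect_share > 0) {
      liab[, j] <- sqrt(spec$effect_share) * (ej / stats::sd(ej)) +
        sqrt(1 - spec$effect_share) * eps[, j]
    } else {
      liab[, j] <- eps[, j]
    }
  }

  counts <- spec$outcome_case_counts
  bin5 <- c(
    "hypertension", "diabetes", "gestational_diabetes",
    "superimposed_preeclampsia", "severe_preeclampsia"
  )
  L <- matrix(0L, n, 6, dimnames = list(NULL, c(bin5, "preterm_birth")))
  for (o in bin5) {
    L[, o] <- threshold_top(liab[, o], counts[[o]])
  }

  # exact GA-at-delivery map: top-`preterm` liabilities land in [24, 37)
  ga <- ga_from_liability(liab[, "ga_delivery"], counts[["preterm_birth"]])
  L[, "preterm_birth"] <- as.integer(ga < 37)

  rep_out <- repair_union(L, liab[, colnames(L)[-6]], ga, spec$n_any_aporf)
  L <- rep_out$labels
  ga <- rep_out$ga

  bmi <- round(pmin(45, pmax(16, 24.5 + 3.8 * liab[, "bmi"])), 1)

  ga_q <- pmin(25, pmax(
    5,
    stats::rlnorm(n, log(spec$ga_questionnaire_median_weeks), 0.3)
  ))

  psf <- observe_psfs(Zl, block, spec$missing_rate)

  cohort <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    ga_questionnaire_weeks = round(ga_q, 1),
    L,
    ga_delivery_weeks = round(ga, 2),
    bmi_prepregnancy = bmi,
    psf$values,
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
  roles <- c(
    patient_id = "meta", ga_questionnaire_weeks = "meta",
    stats::setNames(rep("outcome_binary", 6), colnames(L)),
    ga_delivery_weeks = "outcome_numeric", bmi_prepregnancy = "outcome_numeric",
    stats::setNames(rep("psf", p), colnames(psf$values))
  )
  attr(cohort, "roles") <- roles
  attr(cohort, "outcome_class") <- c(
    hypertension = "rf", diabetes = "rf", bmi_prepregnancy = "rf",
    gestational_diabetes = "apo", superimposed_preeclampsia = "apo",
    severe_preeclampsia = "apo", preterm_birth = "apo",
    ga_delivery_weeks = "apo"
  )
  attr(cohort, "planted") <- list(
    effects = B, liabilities = liab, psf_block = block,
    psf_latent_corr = r, spec = spec
  )
  class(cohort) <- c("cohort_table", "data.frame")
  cohort
}

# 0/1 labels for the k largest liabilities (threshold midway between the
# k-th and (k+1)-th order statistic; continuous liabilities make ties
# measure-zero).
threshold_top <- function(liab, k) {
  n <- length(liab)
  if (k <= 0) {
    return(rep(0L, n))
  }
  if (k >= n) {
    return(rep(1L, n))
  }
  s <- sort(liab, decreasing = TRUE)
  thr <- (s[k] + s[k + 1]) / 2
  as.integer(liab > thr)
}

# Monotone decreasing piecewise-linear map liability -> gestational age in
# weeks with the top-k liabilities mapped into [24, 37) and the rest into
# [37, 42].
ga_from_liability <- function(liab, k) {
  n <- length(liab)
  if (k <= 0) {
    s <- min(liab)
    return(37 + 5 * (max(liab) - liab) / max(max(liab) - s, 1e-9))
  }
  s <- sort(liab, decreasing = TRUE)
  thr <- (s[k] + s[k + 1]) / 2
  ga <- numeric(n)
  hi <- liab > thr
  ga[hi] <- 37 - 12.8 * (liab[hi] - thr) / max(max(liab) - thr, 1e-9) - 0.1
  ga[!hi] <- 37 + 5 * (thr - liab[!hi]) / max(thr - min(liab), 1e-9)
  ga
}

# Greedy minimal label swaps to make the union of positives hit `target`
# exactly while keeping every per-outcome count fixed. Swaps of the
# GA-derived preterm label exchange the two patients' gestational ages so
# labels and GA stay consistent.
repair_union <- function(L, liab5, ga, target) {
  outs <- colnames(L)
  for (iter in seq_len(10 * nrow(L))) {
    affected <- rowSums(L) > 0
    any_n <- sum(affected)
    if (any_n == target) {
      return(list(labels = L, ga = ga))
    }
    if (any_n > target) {
      move <- best_merge_move(L, liab5, ga, affected)
    } else {
      move <- best_split_move(L, liab5, ga, affected)
    }
    if (is.null(move)) {
      stop("union repair failed: no admissible label swap found")
    }
    j <- move$outcome
    if (j == "preterm_birth") {
      tmp <- ga[move$from]
      ga[move$from] <- ga[move$to]
      ga[move$to] <- tmp
    }
    L[move$from, j] <- 0L
    L[move$to, j] <- 1L
  }
  stop("union repair did not converge")
}

# Move a label off a singly-affected donor onto an already-affected receiver
# (shrinks the union by one). Falls back to consolidating moves that keep the
# union fixed but create singletons.
best_merge_move <- function(L, liab5, ga, affected) {
  score <- function(o, pat) {
    if (o == "preterm_birth") -ga[pat] else liab5[pat, o]
  }
  donors <- which(rowSums(L) == 1)
  pick <- NULL
  for (strict in c(TRUE, FALSE)) {
    cand_donors <- if (strict) donors else which(rowSums(L) >= 2)
    for (d in cand_donors) {
      for (o in colnames(L)[L[d, ] == 1L]) {
        recv <- which(affected & L[, o] == 0L & seq_len(nrow(L)) != d)
        if (!length(recv)) next
        r <- recv[which.max(vapply(recv, function(x) score(o, x), 0))]
        gain <- score(o, r) - score(o, d)
        if (is.null(pick) || gain > pick$gain) {
          pick <- list(outcome = o, from = d, to = r, gain = gain)
        }
      }
    }
    if (!is.null(pick)) {
      return(pick)
    }
  }
  NULL
}

# Move one label from a multiply-affected donor onto an unaffected receiver
# (grows the union by one).
best_split_move <- function(L, liab5, ga, affected) {
  score <- function(o, pat) {
    if (o == "preterm_birth") -ga[pat] else liab5[pat, o]
  }
  donors <- which(rowSums(L) >= 2)
  recv0 <- which(!affected)
  if (!length(donors) || !length(recv0)) {
    return(NULL)
  }
  pick <- NULL
  for (d in donors) {
    for (o in colnames(L)[L[d, ] == 1L]) {
      r <- recv0[which.max(vapply(recv0, function(x) score(o, x), 0))]
      gain <- score(o, r) - score(o, d)
      if (is.null(pick) || gain > pick$gain) {
        pick <- list(outcome = o, from = d, to = r, gain = gain)
      }
    }
  }
  pick
}

# Partial discretization of latent Gaussian stressors: cycling ordinal
# (8-point), binary (yes/no at the 60% quantile) and continuous score
# columns, then MCAR missingness.
observe_psfs <- function(Zl, block, missing_rate) {
  p <- ncol(Zl)
  type <- c("ordinal", "binary", "numeric")[(seq_len(p) - 1L) %% 3L + 1L]
  vals <- matrix(NA_real_, nrow(Zl), p)
  cuts <- stats::qnorm(seq_len(7) / 8)
  for (j in seq_len(p)) {
    z <- Zl[, j]
    vals[, j] <- switch(type[j],
      ordinal = findInterval(z, cuts) + 1,
      binary = as.numeric(z > stats::qnorm(0.6)),
      numeric = round(50 + 10 * z, 1)
    )
  }
  if (missing_rate > 0) {
    mask <- matrix(stats::runif(length(vals)) < missing_rate, nrow(vals))
    vals[mask] <- NA_real_
  }
  within <- stats::ave(rep(1, p), block, FUN = seq_along)
  colnames(vals) <- sprintf("psf_%02d_%d", block, within)
  list(values = as.data.frame(vals), type = type)
}

#' Specification of a synthetic single-cell immune panel
#'
#' @param n_immune_patients patients with immune measurements (default 14).
#' @param n_timepoints samples per patient (default 4: three trimesters and
#'   postpartum).
#' @param n_immune_features immune feature columns (default 534).
#' @param n_true_signal_features number of features that are genuinely linear
#'   in the (standardized) stressors plus timepoint.
#' @param n_active_psfs nonzero stressor coefficients per signal feature.
#' @param signal_coefficient_scale standard deviation of planted nonzero
#'   coefficients.
#' @param noise_sd Gaussian noise on signal features (noise features are unit
#'   Gaussian).
#' @param timepoint_effect per-timepoint offsets, default linear in the
#'   1..4 timepoint code so the planted model is exactly representable with a
#'   single timepoint slope.
#' @param seed integer seed.
#' @return object of class `immune_panel_spec`.
#' @export
immune_panel_spec <- function(n_immune_patients = 14,
                              n_timepoints = 4,
                              n_immune_features = 534,
                              n_true_signal_features = 40,
                              n_active_psfs = 5,
                              signal_coefficient_scale = 1,
                              noise_sd = 1,
                              timepoint_effect = 0.5 * (seq_len(n_timepoints) - 1),
                              seed = 1L) {
  stopifnot(
    n_true_signal_features <= n_immune_features,
    noise_sd >= 0,
    length(timepoint_effect) == n_timepoints
  )
  structure(
    list(
      n_immune_patients = n_immune_patients,
      n_timepoints = n_timepoints,
      n_immune_features = n_immune_features,
      n_true_signal_features = n_true_signal_features,
      n_active_psfs = n_active_psfs,
      signal_coefficient_scale = signal_coefficient_scale,
      noise_sd = noise_sd,
      timepoint_effect = timepoint_effect,
      seed = as.integer(seed)
    ),
    class = "immune_panel_spec"
  )
}

#' Generate a synthetic immune panel for a subset of the cohort
#'
#' Samples `n_immune_patients` patients and emits `n_timepoints` rows per
#' patient. The first `n_true_signal_features` feature columns are linear in
#' the cohort-standardized stressors (sparse planted coefficients) plus a
#' per-timepoint offset and Gaussian noise; the remaining columns are pure
#' noise. The planted truth (coefficients, offsets, the standardization used)
#' is returned in `$truth` for recovery tests.
#'
#' @param cohort a `cohort_table`.
#' @param spec an [immune_panel_spec()].
#' @return object of class `immune_panel`: list with `values`
#'   (rows x features matrix), `patient_id`, `timepoint`, `feature_names` and
#'   `truth`.
#' @export
generate_immune_panel <- function(cohort, spec) {
  stopifnot(inherits(spec, "immune_panel_spec"))
  if (spec$n_immune_patients > nrow(cohort)) {
    stop("n_immune_patients exceeds cohort size")
  }
  set.seed(spec$seed)
  pats <- sort(sample(cohort$patient_id, spec$n_immune_patients))
  psf_cols <- names(which(attr(cohort, "roles") == "psf"))
  X <- as.matrix(cohort[, psf_cols, drop = FALSE])
  std <- standardize_by_fit(X)
  Xs <- std$values
  rownames(Xs) <- cohort$patient_id

  k <- spec$n_true_signal_features
  m <- spec$n_immune_features
  p <- length(psf_cols)
  beta <- matrix(0, p, m, dimnames = list(psf_cols, NULL))
  if (k > 0) {
    for (j in seq_len(k)) {
      nz <- sample(p, min(spec$n_active_psfs, p))
      beta[nz, j] <- stats::rnorm(
        length(nz), 0, spec$signal_coefficient_scale
      )
    }
  }
  feature_names <- sprintf("imm_%03d", seq_len(m))
  colnames(beta) <- feature_names

  nrows <- spec$n_immune_patients * spec$n_timepoints
  patient_id <- rep(pats, each = spec$n_timepoints)
  timepoint <- rep(seq_len(spec$n_timepoints), spec$n_immune_patients)
  V <- matrix(stats::rnorm(nrows * m), nrows, m,
    dimnames = list(NULL, feature_names)
  )
  if (k > 0) {
    base <- Xs[patient_id, , drop = FALSE] %*% beta[, seq_len(k), drop = FALSE]
    off <- spec$timepoint_effect[timepoint]
    noise <- if (spec$noise_sd > 0) {
      matrix(stats::rnorm(nrows * k, 0, spec$noise_sd), nrows, k)
    } else {
      0
    }
    V[, seq_len(k)] <- base + off + noise
  }
  structure(
    list(
      values = V,
      patient_id = patient_id,
      timepoint = timepoint,
      feature_names = feature_names,
      truth = list(
        beta = beta,
        signal_features = feature_names[seq_len(k)],
        timepoint_effect = spec$timepoint_effect,
        patients = pats,
        psf_center = std$center,
        psf_sd = std$sd
      ),
      spec = spec
    ),
    class = "immune_panel"
  )
}

#' Generate a raw questionnaire fixture exercising the documented filter chain
#'
#' Emits a 283-patient raw questionnaire containing free-text columns, a
#' parseable "preferred bedtime" text column, constant and all-missing
#' columns, the age-inapplicable "life stress 41-50" item, and 78 numeric
#' items - engineered so that after excluding the 83 patients without
#' preeclampsia information and applying the documented filter chain, exactly
#' 79 predictors remain (the 78 numeric items plus the parsed bedtime). A
#' matching 283-row outcome table is returned alongside, with both
#' preeclampsia fields missing for 83 patients.
#'
#' @param seed integer seed.
#' @param n_patients total patients in the raw table.
#' @param n_missing_pree patients lacking any preeclampsia information.
#' @return list with `questionnaire` and `outcomes` data frames.
#' @export
generate_questionnaire_fixture <- function(seed = 1L, n_patients = 283,
                                           n_missing_pree = 83) {
  stopifnot(n_missing_pree <= n_patients)
  set.seed(as.integer(seed))
  n <- n_patients
  id <- sprintf("Q%03d", seq_len(n))

  bedtimes <- c(
    "9:00 PM", "9:30 PM", "10:00 PM", "10:30 PM", "11:00 PM",
    "11:30 PM", "12:00 AM", "12:30 AM", "1:00 AM", "whenever", "varies"
  )
  items <- matrix(sample(0:7, n * 78, replace = TRUE), n, 78)
  # guarantee every item keeps at least two observed values after any
  # downstream row subset: fix the first two rows of each column
  items[1, ] <- 0
  items[2, ] <- 7
  colnames(items) <- sprintf("item_%03d", seq_len(78))
  miss <- matrix(stats::runif(n * 78) < 0.03, n, 78)
  items[miss] <- NA

  q <- data.frame(
    patient_id = id,
    occupation_text = sample(
      c("teacher", "engineer", "nurse", "student", "clerk"), n, TRUE
    ),
    notes_text = sample(c("none", "see chart", "n/a"), n, TRUE),
    preferred_bedtime = sample(bedtimes, n, TRUE,
      prob = c(rep(0.105, 9), 0.03, 0.025)
    ),
    constant_item = 3,
    all_missing_item = NA_real_,
    life_stress_41_50 = sample(0:7, n, TRUE),
    items,
    check.names = FALSE,
    stringsAsFactors = FALSE
  )

  missing_pree <- sample(n, n_missing_pree)
  sev <- stats::rbinom(n, 1, 0.065)
  sup <- stats::rbinom(n, 1, 0.03)
  sev[missing_pree] <- NA
  sup[missing_pree] <- NA
  outcomes <- data.frame(
    patient_id = id,
    severe_preeclampsia = sev,
    superimposed_preeclampsia = sup,
    gestational_diabetes = stats::rbinom(n, 1, 0.145),
    stringsAsFactors = FALSE
  )
  list(questionnaire = q, outcomes = outcomes)
}
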