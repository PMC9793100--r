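# Shared fixtures, built in code at test time.

# A small cohort spec (40 patients, 4 blocks of 3 stressors) for fast tests.
small_cohort_spec <- function(seed = 1L, ...) {
  args <- list(
    n_patients = 40,
    outcome_case_counts = c(
      hypertension = 6, diabetes = 4, gestational_diabetes = 8,
      superimposed_preeclampsia = 2, severe_preeclampsia = 4,
      preterm_birth = 5
    ),
    n_any_aporf = 14,
    psf_block_sizes = rep(3, 4),
    psf_effect_matrix = matrix(0, 12, 7),
    missing_rate = 0.05,
    seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(cohort_spec, args)
}

# Stressor feature matrix straight from a cohort table's PSF columns.
cohort_features <- function(cohort) {
  psf <- names(which(attr(cohort, "roles") == "psf"))
  filter_features(
    cbind(
      data.frame(patient_id = cohort$patient_id, stringsAsFactors = FALSE),
      cohort[, psf, drop = FALSE]
    ),
    drop_items = character()
  )
}

# A spec whose PSFs genuinely drive two correlated binary outcomes, one
# rare: the borrowing-strength scenario for the multitask comparison.
paired_outcome_spec <- function(latent_corr, shared_effects, n_any, seed = 1L) {
  nm <- c(
    "hypertension", "diabetes", "gestational_diabetes",
    "superimposed_preeclampsia", "severe_preeclampsia",
    "ga_delivery", "bmi"
  )
  R <- diag(7)
  dimnames(R) <- list(nm, nm)
  R["hypertension", "diabetes"] <- latent_corr
  R["diabetes", "hypertension"] <- latent_corr
  blocks <- rep(seq_along(default_psf_blocks()), default_psf_blocks())
  B <- matrix(0, 79, 7, dimnames = list(NULL, nm))
  B[blocks %in% 1:2, "hypertension"] <- 1
  B[blocks %in% (if (shared_effects) 1:2 else 3:4), "diabetes"] <- 1
  cohort_spec(
    outcome_case_counts = c(
      hypertension = 50, diabetes = 10, gestational_diabetes = 0,
      superimposed_preeclampsia = 0, severe_preeclampsia = 0,
      preterm_birth = 0
    ),
    n_any_aporf = n_any,
    outcome_latent_corr = R,
    psf_effect_matrix = B,
    seed = seed
  )
}

# Brute-force oracles -------------------------------------------------------

# Spearman via the classical no-ties formula 1 - 6*sum(d^2)/(n(n^2-1)).
oracle_spearman_noties <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# AUROC by exhaustive concordance over positive/negative pairs.
oracle_auroc <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  tot <- 0
  for (a in pos) {
    for (b in neg) {
      tot <- tot + (a > b) + 0.5 * (a == b)
    }
  }
  tot / (length(pos) * length(neg))
}

# Benjamini-Hochberg by literal step-up enumeration.
oracle_bh_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(m)) {
    if (ps[i] <= i * alpha / m) k <- i
  }
  rej <- rep(FALSE, m)
  if (k > 0) rej[o[seq_len(k)]] <- TRUE
  rej
}

# Exact two-sided signed-rank p-value by enumerating all sign assignments
# (no zeros, no tied absolute differences; n <= 12).
oracle_signed_rank_p <- function(d) {
  n <- length(d)
  stopifnot(n <= 12, all(d != 0))
  r <- rank(abs(d))
  stopifnot(!anyDuplicated(r))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  null_v <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  mean(abs(null_v - mu) >= abs(v - mu) - 1e-9)
}
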