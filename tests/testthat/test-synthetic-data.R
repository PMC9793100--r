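test_that("cohort generation is deterministic and hits case counts exactly", {
  sp <- small_cohort_spec(seed = 11)
  a <- generate_cohort(sp)
  b <- generate_cohort(sp)
  expect_identical(a, b)

  counts <- sp$outcome_case_counts
  for (o in names(counts)) {
    expect_equal(sum(a[[o]]), unname(counts[[o]]), info = o)
  }
  expect_equal(sum(rowSums(a[, names(counts)]) > 0), sp$n_any_aporf)
  expect_equal(sum(a$ga_delivery_weeks < 37), unname(counts[["preterm_birth"]]))
})

test_that("case counts and union size hold over random feasible specs", {
  set.seed(20)
  for (i in 1:8) {
    counts <- c(
      hypertension = sample(0:10, 1), diabetes = sample(0:10, 1),
      gestational_diabetes = sample(0:12, 1),
      superimposed_preeclampsia = sample(0:4, 1),
      severe_preeclampsia = sample(0:6, 1),
      preterm_birth = sample(0:8, 1)
    )
    lo <- max(counts)
    hi <- min(40, sum(counts))
    n_any <- if (hi > lo) sample(lo:hi, 1) else lo
    sp <- small_cohort_spec(
      seed = 100 + i, outcome_case_counts = counts, n_any_aporf = n_any
    )
    co <- generate_cohort(sp)
    expect_equal(unname(colSums(co[, names(counts)])), unname(counts))
    expect_equal(sum(rowSums(co[, names(counts)]) > 0), n_any)
  }
})

test_that("all-zero case counts give an all-negative label matrix", {
  counts <- c(
    hypertension = 0, diabetes = 0, gestational_diabetes = 0,
    superimposed_preeclampsia = 0, severe_preeclampsia = 0,
    preterm_birth = 0
  )
  co <- generate_cohort(
    small_cohort_spec(outcome_case_counts = counts, n_any_aporf = 0)
  )
  expect_true(all(co[, names(counts)] == 0))
})

test_that("infeasible union sizes are rejected with the violated bound", {
  expect_error(small_cohort_spec(n_any_aporf = 3), "infeasible")
  expect_error(small_cohort_spec(n_any_aporf = 35), "infeasible")
})

test_that("within-block stressor correlation exceeds between-block correlation", {
  sp <- cohort_spec(
    n_patients = 300,
    psf_block_sizes = rep(5, 5), psf_block_corr = 0.9,
    psf_effect_matrix = matrix(0, 25, 7),
    missing_rate = 0, seed = 5
  )
  co <- generate_cohort(sp)
  psf <- as.matrix(co[, grep("^psf_", names(co))])
  R <- abs(stats::cor(psf, method = "spearman"))
  block <- rep(1:5, each = 5)
  same <- outer(block, block, "==") & upper.tri(R)
  diff <- outer(block, block, "!=") & upper.tri(R)
  expect_gt(mean(R[same]), mean(R[diff]))
})

test_that("latent binary co-occurrence is monotone in the configured correlation", {
  phis <- sapply(c(0, 0.5, 0.95), function(r) {
    R <- diag(7)
    dimnames(R) <- list(
      colnames(default_outcome_corr()), colnames(default_outcome_corr())
    )
    R["hypertension", "diabetes"] <- R["diabetes", "hypertension"] <- r
    sp <- cohort_spec(
      n_patients = 5000,
      outcome_case_counts = c(
        hypertension = 500, diabetes = 400, gestational_diabetes = 0,
        superimposed_preeclampsia = 0, severe_preeclampsia = 0,
        preterm_birth = 0
      ),
      n_any_aporf = if (r == 0) 860 else if (r == 0.5) 750 else 520,
      outcome_latent_corr = R,
      psf_effect_matrix = matrix(0, 79, 7),
      seed = 31
    )
    co <- generate_cohort(sp)
    stats::cor(co$hypertension, co$diabetes)
  })
  expect_true(all(diff(phis) > 0))
})

test_that("immune panel has the requested patient-timepoint structure", {
  co <- generate_cohort(small_cohort_spec())
  pan <- generate_immune_panel(
    co, immune_panel_spec(
      n_immune_patients = 14, n_timepoints = 4,
      n_immune_features = 30, n_true_signal_features = 5, seed = 8
    )
  )
  expect_equal(length(unique(pan$patient_id)), 14)
  expect_true(all(table(pan$patient_id) == 4))
  expect_equal(dim(pan$values), c(56, 30))
  expect_error(
    generate_immune_panel(co, immune_panel_spec(n_immune_patients = 50)),
    "exceeds cohort size"
  )
})

test_that("noiseless signal features are exact linear functions of PSFs + timepoint", {
  co <- generate_cohort(small_cohort_spec(missing_rate = 0))
  pan <- generate_immune_panel(
    co, immune_panel_spec(
      n_immune_patients = 14, n_immune_features = 10,
      n_true_signal_features = 3, noise_sd = 0, seed = 4
    )
  )
  fm <- cohort_features(co)
  idx <- match(pan$patient_id, fm$patient_id)
  Xs <- sweep(
    sweep(fm$values[idx, ], 2, pan$truth$psf_center), 2, pan$truth$psf_sd, "/"
  )
  X <- add_timepoint(Xs, pan$timepoint)
  for (j in 1:3) {
    f <- ridge_fit(X, pan$values[, j], alpha = 0)
    resid <- pan$values[, j] - (X %*% matrix(f$coef) + f$intercept)
    expect_lt(max(abs(resid)), 1e-8)
  }
})

test_that("exact refit on an identifiable noiseless panel recovers planted coefficients", {
  co <- generate_cohort(
    small_cohort_spec(n_patients = 60, psf_block_sizes = rep(3, 4), missing_rate = 0)
  )
  pan <- generate_immune_panel(
    co, immune_panel_spec(
      n_immune_patients = 30, n_immune_features = 8,
      n_true_signal_features = 4, noise_sd = 0, seed = 9
    )
  )
  fm <- cohort_features(co)
  idx <- match(pan$patient_id, fm$patient_id)
  Xs <- sweep(
    sweep(fm$values[idx, ], 2, pan$truth$psf_center), 2, pan$truth$psf_sd, "/"
  )
  X <- add_timepoint(Xs, pan$timepoint)
  for (j in 1:4) {
    f <- ridge_fit(X, pan$values[, j], alpha = 0)
    expect_equal(
      unname(f$coef[seq_len(ncol(fm$values))]),
      unname(pan$truth$beta[, j]),
      tolerance = 1e-6
    )
  }
})

test_that("signal-free panels show no stressor association beyond the null", {
  co <- generate_cohort(small_cohort_spec(n_patients = 30, missing_rate = 0, seed = 3))
  pan <- generate_immune_panel(
    co, immune_panel_spec(
      n_immune_patients = 30, n_immune_features = 12,
      n_true_signal_features = 0, seed = 6
    )
  )
  fm <- cohort_features(co)
  idx <- match(pan$patient_id, fm$patient_id)
  X <- fm$values[idx, ]
  obs <- abs(stats::cor(X, pan$values, method = "spearman"))
  # per-pair permutation null quantile of |rho| at this sample size
  set.seed(99)
  null_rho <- replicate(4000, {
    abs(stats::cor(sample(X[, 1]), pan$values[, 1], method = "spearman"))
  })
  expect_lt(max(obs), stats::quantile(null_rho, 0.999))
})

test_that("questionnaire fixture is deterministic and exercises every filter rule", {
  fx <- generate_questionnaire_fixture(7)
  fx2 <- generate_questionnaire_fixture(7)
  expect_identical(fx, fx2)
  expect_equal(nrow(fx$questionnaire), 283)
  expect_equal(sum(rowSums(!is.na(
    fx$outcomes[, c("severe_preeclampsia", "superimposed_preeclampsia")]
  )) == 0), 83)
  expect_true(is.character(fx$questionnaire$occupation_text))
  expect_true(all(is.na(fx$questionnaire$all_missing_item)))
  expect_true(length(unique(fx$questionnaire$constant_item)) == 1)
})
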