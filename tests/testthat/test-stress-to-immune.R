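test_that("ridge_fit matches the closed-form normal equations and OLS limits", {
  # exact proportionality, no penalty
  x <- matrix(c(1, 2, 3, 4), ncol = 1)
  f <- ridge_fit(x, 2 * x[, 1], alpha = 0)
  expect_equal(unname(f$coef), 2)

  # fixed 3x2 system vs (X'X + aI)^-1 X'y, no intercept
  X <- matrix(c(1, 2, 0, -1, 1, 3), 3, 2)
  y <- c(1, 0, 2)
  f2 <- ridge_fit(X, y, alpha = 0.1, intercept = FALSE)
  oracle <- solve(crossprod(X) + diag(0.1, 2), crossprod(X, y))
  expect_equal(unname(f2$coef), drop(oracle), tolerance = 1e-10)

  # with intercept: centered closed form
  f3 <- ridge_fit(X, y, alpha = 0.5)
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  oracle3 <- solve(crossprod(Xc) + diag(0.5, 2), crossprod(Xc, yc))
  expect_equal(unname(f3$coef), drop(oracle3), tolerance = 1e-10)
  expect_equal(f3$intercept, mean(y) - sum(colMeans(X) * f3$coef))
})

test_that("coefficient norms shrink monotonically in alpha and alpha=0 is minimum-norm", {
  set.seed(30)
  X <- matrix(rnorm(12 * 20), 12, 20) # p > n
  y <- rnorm(12)
  alphas <- c(0, 1e-4, 1e-3, 0.01, 0.1, 1)
  norms <- vapply(
    alphas, function(a) sqrt(sum(ridge_fit(X, y, a)$coef^2)), 0
  )
  expect_true(all(diff(norms) <= 1e-8))
  # minimum-norm solution interpolates the centered system
  f0 <- ridge_fit(X, y, 0)
  expect_lt(max(abs(X %*% f0$coef + f0$intercept - y)), 1e-8)
})

test_that("add_timepoint appends the raw code column in row order", {
  X <- matrix(1, 4, 2)
  A <- add_timepoint(X, c(1, 2, 3, 4))
  expect_equal(unname(A[, 3]), c(1, 2, 3, 4))
  expect_equal(colnames(A)[3], "timepoint")
  shuf <- add_timepoint(X, c(3, 1, 4, 2))
  expect_equal(unname(shuf[, 3]), c(3, 1, 4, 2))
  expect_equal(ncol(add_timepoint(X[0, , drop = FALSE], integer(0))), 3)
  expect_error(add_timepoint(X, c(1, 2, 3, 5)), "unknown timepoint")
})

test_that("bh_correct reproduces the step-up rule and its oracle", {
  r <- bh_correct(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_true(all(r$rejected))
  expect_equal(sum(bh_correct(c(0.001, 0.8, 0.9))$rejected), 1)
  expect_false(any(bh_correct(rep(1, 5))$rejected))
  expect_true(all(diff(sort(r$q)) >= 0))

  set.seed(40)
  for (i in 1:20) {
    m <- sample(3:30, 1)
    p <- runif(m)^2 # continuous draws: q == alpha has measure zero
    got <- bh_correct(p, alpha = 0.05)
    expect_equal(got$rejected, oracle_bh_reject(p, 0.05))
    expect_equal(got$q, stats::p.adjust(p, "BH"))
  }
})

test_that("grouped folds keep every patient's timepoints together", {
  co <- generate_cohort(small_cohort_spec(seed = 15))
  fm <- cohort_features(co)
  pan <- generate_immune_panel(
    co, immune_panel_spec(
      n_immune_patients = 14, n_immune_features = 20,
      n_true_signal_features = 4, seed = 2
    )
  )
  cv <- grouped_repeated_cv(pan, fm, ridge_config(n_repetitions = 2, seed = 7))
  for (s in cv$ensemble$slices) {
    expect_true(all(table(pan$patient_id) == 4))
  }
  # reconstruct fold membership per repetition and check group integrity
  for (r in 1:2) {
    set.seed(7 + r)
    folds <- pregstress:::grouped_folds(pan$patient_id, 10)
    expect_equal(sort(unlist(folds)), seq_along(pan$patient_id))
    for (f in folds) {
      pats <- unique(pan$patient_id[f])
      expect_true(all(!pan$patient_id[-f] %in% pats))
    }
  }
  expect_error(
    grouped_repeated_cv(
      generate_immune_panel(co, immune_panel_spec(n_immune_patients = 5)),
      fm, ridge_config()
    ),
    "fewer patients"
  )
})

test_that("an exactly linear immune feature is recovered as significant with rho near 1", {
  co <- generate_cohort(
    small_cohort_spec(n_patients = 60, psf_block_sizes = rep(3, 4), missing_rate = 0)
  )
  fm <- cohort_features(co)
  pan <- generate_immune_panel(
    co, immune_panel_spec(
      n_immune_patients = 16, n_immune_features = 12,
      n_true_signal_features = 3, noise_sd = 0, seed = 3
    )
  )
  cv <- grouped_repeated_cv(pan, fm, ridge_config(n_repetitions = 2, seed = 5))
  pr <- cv$predictability
  sig <- pr$immune_feature %in% pan$truth$signal_features
  expect_true(all(pr$significant[sig]))
  expect_gte(min(pr$mean_rho[sig]), 0.99)
})

test_that("averaged ensemble coefficients recover planted coefficients at low noise", {
  co <- generate_cohort(
    cohort_spec(
      n_patients = 120, psf_block_sizes = rep(4, 5),
      psf_effect_matrix = matrix(0, 20, 7),
      outcome_case_counts = c(
        hypertension = 12, diabetes = 8, gestational_diabetes = 18,
        superimposed_preeclampsia = 4, severe_preeclampsia = 8,
        preterm_birth = 10
      ),
      n_any_aporf = 36, seed = 19
    )
  )
  fm <- cohort_features(co)
  pan <- generate_immune_panel(
    co, immune_panel_spec(
      n_immune_patients = 25, n_immune_features = 40,
      n_true_signal_features = 8, noise_sd = 0.05, seed = 5
    )
  )
  cv <- grouped_repeated_cv(pan, fm, ridge_config(n_repetitions = 3, seed = 11))
  gen <- average_ensemble(cv$ensemble)
  sigf <- pan$truth$signal_features
  W <- gen$W[sigf, setdiff(gen$predictor_names, "timepoint")]
  B <- t(pan$truth$beta[, sigf])
  expect_gte(stats::cor(as.vector(W), as.vector(B)), 0.9)
})

test_that("alpha selection never sees held-out data", {
  co <- generate_cohort(small_cohort_spec(seed = 23))
  fm <- cohort_features(co)
  pan <- generate_immune_panel(
    co, immune_panel_spec(
      n_immune_patients = 14, n_immune_features = 10,
      n_true_signal_features = 3, seed = 4
    )
  )
  cfg <- ridge_config(n_repetitions = 1, seed = 13)
  cv1 <- grouped_repeated_cv(pan, fm, cfg)
  # poison one patient's immune values; slices whose TEST fold holds that
  # patient must be identical (training never touched those rows)
  poisoned <- pan
  victim <- pan$truth$patients[1]
  poisoned$values[pan$patient_id == victim, ] <- 1e3
  cv2 <- grouped_repeated_cv(poisoned, fm, cfg)
  hit <- vapply(
    cv1$ensemble$slices, function(s) victim %in% s$test_patients, TRUE
  )
  expect_true(any(hit))
  for (i in which(hit)) {
    expect_identical(
      cv1$ensemble$slices[[i]]$coef, cv2$ensemble$slices[[i]]$coef
    )
    expect_identical(
      cv1$ensemble$slices[[i]]$alpha, cv2$ensemble$slices[[i]]$alpha
    )
  }
})

test_that("mean_p is the arithmetic mean of per-repetition p-values", {
  co <- generate_cohort(small_cohort_spec(seed = 24))
  fm <- cohort_features(co)
  pan <- generate_immune_panel(
    co, immune_panel_spec(
      n_immune_patients = 14, n_immune_features = 8,
      n_true_signal_features = 2, seed = 5
    )
  )
  cv <- grouped_repeated_cv(pan, fm, ridge_config(n_repetitions = 3, seed = 2))
  pr <- cv$predictability
  p_rep <- attr(pr, "per_repetition_p")
  expect_equal(pr$mean_p, unname(colMeans(p_rep)))
  rho_rep <- attr(pr, "per_repetition_rho")
  expect_equal(pr$mean_rho, unname(colMeans(rho_rep)))
  expect_identical(pr$significant, pr$q < 0.05)
})

test_that("the count of discoveries grows with the planted signal scale", {
  co <- generate_cohort(small_cohort_spec(n_patients = 60, seed = 25))
  fm <- cohort_features(co)
  counts <- vapply(c(0.2, 1, 4), function(scl) {
    pan <- generate_immune_panel(
      co, immune_panel_spec(
        n_immune_patients = 14, n_immune_features = 30,
        n_true_signal_features = 10, signal_coefficient_scale = scl,
        noise_sd = 1, seed = 6
      )
    )
    cv <- grouped_repeated_cv(pan, fm, ridge_config(n_repetitions = 2, seed = 9))
    sum(cv$predictability$significant)
  }, 0)
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[3], counts[1])
})
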