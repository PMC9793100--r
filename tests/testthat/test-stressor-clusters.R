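test_that("correlation profiles are symmetric with unit diagonal", {
  co <- generate_cohort(small_cohort_spec(seed = 9))
  fm <- cohort_features(co)
  P <- correlation_profiles(fm)
  expect_equal(P, t(P))
  expect_true(all(diag(P) == 1))

  # identical features have identical profiles and mutual rho 1
  fm2 <- fm
  fm2$values <- cbind(fm$values, dup = fm$values[, 1])
  fm2$feature_names <- c(fm$feature_names, "dup")
  P2 <- correlation_profiles(fm2)
  expect_equal(P2["dup", 1], 1)
  expect_equal(unname(P2["dup", -c(1, ncol(P2))]), unname(P2[1, -c(1, ncol(P2))]))
})

test_that("planted blocks are closer in profile space within than between", {
  sp <- cohort_spec(
    n_patients = 250, psf_block_sizes = rep(5, 3), psf_block_corr = 0.7,
    psf_effect_matrix = matrix(0, 15, 7), missing_rate = 0, seed = 12
  )
  co <- generate_cohort(sp)
  P <- correlation_profiles(cohort_features(co))
  D <- as.matrix(stats::dist(P))
  block <- rep(1:3, each = 5)
  same <- outer(block, block, "==") & upper.tri(D)
  diff <- outer(block, block, "!=") & upper.tri(D)
  expect_lt(mean(D[same]), mean(D[diff]))
})

test_that("k-means on correlation profiles yields k non-empty clusters", {
  co <- generate_cohort(cohort_spec())
  P <- correlation_profiles(cohort_features(co))
  cl <- cluster_psfs(P, k = 15, seed = 2)
  expect_equal(sort(unique(cl$assignment$cluster)), 1:15)
  expect_equal(nrow(cl$assignment), 79)

  cl1 <- cluster_psfs(P, k = 1, seed = 2)
  expect_true(all(cl1$assignment$cluster == 1))
  expect_error(cluster_psfs(P[1:4, 1:4], k = 10), "exceeds")

  # determinism given the seed
  cl2 <- cluster_psfs(P, k = 15, seed = 2)
  expect_identical(cl$assignment, cl2$assignment)
})

test_that("planted stressor blocks are recovered at high adjusted Rand index", {
  skip_if_not_installed("mclust")
  sp <- cohort_spec(
    n_patients = 250, psf_block_sizes = rep(6, 5), psf_block_corr = 0.6,
    psf_effect_matrix = matrix(0, 30, 7), seed = 21
  )
  co <- generate_cohort(sp)
  P <- correlation_profiles(cohort_features(co))
  cl <- cluster_psfs(P, k = 5, seed = 3)
  truth <- rep(1:5, each = 6)
  ari <- mclust::adjustedRandIndex(cl$assignment$cluster, truth)
  expect_gte(ari, 0.9)
})

test_that("the embedding has the right shape and respects profile geometry", {
  sp <- cohort_spec(
    n_patients = 250, psf_block_sizes = rep(5, 3), psf_block_corr = 0.7,
    psf_effect_matrix = matrix(0, 15, 7), missing_rate = 0, seed = 12
  )
  co <- generate_cohort(sp)
  P <- correlation_profiles(cohort_features(co))
  Y <- embed_psfs(P, seed = 4)
  expect_equal(dim(Y), c(15, 2))
  expect_identical(Y, embed_psfs(P, seed = 4)) # deterministic

  D <- as.matrix(stats::dist(Y))
  block <- rep(1:3, each = 5)
  same <- outer(block, block, "==") & upper.tri(D)
  diff <- outer(block, block, "!=") & upper.tri(D)
  expect_lt(mean(D[same]), mean(D[diff]))
})

test_that("duplicate and sign-flipped features embed together but cluster apart", {
  set.seed(6)
  X <- matrix(rnorm(150 * 30), 150, 30)
  X <- cbind(X, X[, 1], -X[, 1]) # exact duplicate and sign flip of feature 1
  colnames(X) <- c(sprintf("f%d", 1:30), "dup", "flip")
  P <- correlation_profiles(X)
  Y <- embed_psfs(P, seed = 7)
  diam <- max(stats::dist(Y))
  # raw profiles of f1 and dup coincide; |profiles| also pull in the flip
  expect_lt(sqrt(sum((Y["f1", ] - Y["dup", ])^2)), 0.01 * diam)
  expect_lt(sqrt(sum((Y["f1", ] - Y["flip", ])^2)), 0.15 * diam)
  # clustering uses SIGNED profiles: the flip must not join f1's cluster
  cl <- cluster_psfs(P, k = 2, seed = 8)
  a <- cl$assignment
  expect_equal(
    a$cluster[a$feature == "f1"], a$cluster[a$feature == "dup"]
  )
  expect_false(
    a$cluster[a$feature == "f1"] == a$cluster[a$feature == "flip"]
  )
})

test_that("association counts, percentages and the any-member rule are exact", {
  # constructed toy input: 4 stressors in one cluster, exactly one of which
  # tracks the outcome
  set.seed(11)
  n <- 120
  out <- rbinom(n, 1, 0.3)
  X <- cbind(
    s1 = out + rnorm(n, sd = 0.2), # strongly associated
    s2 = rnorm(n), s3 = rnorm(n), s4 = rnorm(n)
  )
  outcomes <- data.frame(
    patient_id = seq_len(n), hypertension = out,
    diabetes = rbinom(n, 1, 0.2)
  )
  attr(outcomes, "outcome_class") <- c(hypertension = "rf", diabetes = "rf")
  clusters <- structure(
    list(
      assignment = data.frame(
        feature = colnames(X), cluster = rep(1L, 4),
        stringsAsFactors = FALSE
      ),
      k = 1, centers = NULL, seed_used = 1L
    ),
    class = "cluster_assignment"
  )
  res <- associate(X, outcomes, clusters, tasks = c("hypertension", "diabetes"))
  expect_true(res$significant["s1", "hypertension"])
  expect_equal(sum(res$significant[, "hypertension"]), 1)
  cs <- res$cluster_summary[[1]]
  expect_equal(unname(cs$pct_significant_per_aporf[["hypertension"]]), 25)
  expect_equal(cs$n_assoc_aporfs, sum(colSums(res$significant) > 0))
  # masked heatmap hides exactly the non-significant cells
  expect_true(is.na(res$rho_masked["s2", "hypertension"]))
  expect_false(is.na(res$rho_masked["s1", "hypertension"]))
  # significance uses RAW p-values at alpha, no multiplicity correction
  expect_identical(res$significant, !is.na(res$p) & res$p < res$alpha)
})

test_that("a stressor identical to an outcome is counted for that outcome", {
  co <- generate_cohort(small_cohort_spec(seed = 13))
  fm <- cohort_features(co)
  fm$values <- cbind(fm$values, leak = co$gestational_diabetes)
  fm$feature_names <- c(fm$feature_names, "leak")
  P <- correlation_profiles(fm)
  cl <- cluster_psfs(P, k = 3, seed = 1)
  res <- associate(fm, co, cl)
  expect_lt(res$p["leak", "gestational_diabetes"], 1e-10)
  expect_true(res$significant["leak", "gestational_diabetes"])
})

test_that("cluster summaries are invariant to feature order", {
  co <- generate_cohort(small_cohort_spec(seed = 3))
  fm <- cohort_features(co)
  P <- correlation_profiles(fm)
  cl <- cluster_psfs(P, k = 3, seed = 5)
  r1 <- associate(fm, co, cl)
  perm <- rev(seq_along(fm$feature_names))
  fm2 <- fm
  fm2$values <- fm$values[, perm]
  fm2$feature_names <- fm$feature_names[perm]
  r2 <- associate(fm2, co, cl)
  for (i in seq_along(r1$cluster_summary)) {
    expect_equal(
      r1$cluster_summary[[i]]$n_assoc_aporfs,
      r2$cluster_summary[[i]]$n_assoc_aporfs
    )
    expect_equal(
      r1$cluster_summary[[i]]$pct_significant_per_aporf,
      r2$cluster_summary[[i]]$pct_significant_per_aporf
    )
  }
})
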