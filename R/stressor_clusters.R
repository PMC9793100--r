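#' Spearman correlation profiles of the stressors
#'
#' Row `i` is the vector of Spearman correlations (pairwise-complete) of
#' stressor `i` against every stressor, with unit diagonal. Stressors whose
#' profile is entirely undefined (no complete pairs or zero variance against
#' everything) are excluded with a warning.
#'
#' @param fm a `feature_matrix`.
#' @return square numeric matrix of profiles (features x features).
#' @export
correlation_profiles <- function(fm) {
  X <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  nm <- if (inherits(fm, "feature_matrix")) fm$feature_names else colnames(X)
  stopifnot(ncol(X) >= 2)
  P <- suppressWarnings(
    stats::cor(X, method = "spearman", use = "pairwise.complete.obs")
  )
  dimnames(P) <- list(nm, nm)
  diag(P) <- 1
  undef <- vapply(seq_len(nrow(P)), function(i) all(is.na(P[i, -i])), TRUE)
  if (any(undef)) {
    warning(
      "excluding ", sum(undef),
      " stressor(s) with undefined correlation profiles: ",
      paste(utils::head(nm[undef], 5), collapse = ", ")
    )
    P <- P[!undef, !undef, drop = FALSE]
  }
  P[is.na(P)] <- 0
  P
}

#' Cluster stressors by their correlation profiles
#'
#' K-means on the raw (signed) correlation vectors, 10 restarts, fixed seed.
#' The run is re-seeded (deterministically) if an empty cluster arises, so
#' all `k` clusters are non-empty.
#'
#' @param profiles correlation-profile matrix from [correlation_profiles()].
#' @param k number of clusters (default 15, the number of stressor
#'   categories).
#' @param seed integer seed.
#' @param nstart K-means restarts.
#' @return object of class `cluster_assignment`: list with `assignment`
#'   (data frame: feature, cluster), `k`, `centers` and `seed_used`.
#' @export
cluster_psfs <- function(profiles, k = 15, seed = 1L, nstart = 10) {
  profiles <- as.matrix(profiles)
  if (k > nrow(profiles)) {
    stop("k (", k, ") exceeds the number of stressors (", nrow(profiles), ")")
  }
  km <- NULL
  seed_used <- as.integer(seed)
  for (try in seq_len(25)) {
    set.seed(seed_used)
    km <- tryCatch(
      stats::kmeans(profiles, centers = k, nstart = nstart, iter.max = 100),
      error = function(e) NULL
    )
    if (!is.null(km) && length(unique(km$cluster)) == k) break
    km <- NULL
    seed_used <- seed_used + 1000L
  }
  if (is.null(km)) {
    stop("k-means failed to produce ", k, " non-empty clusters")
  }
  structure(
    list(
      assignment = data.frame(
        feature = rownames(profiles),
        cluster = unname(km$cluster),
        stringsAsFactors = FALSE
      ),
      k = k,
      centers = km$centers,
      seed_used = seed_used
    ),
    class = "cluster_assignment"
  )
}

#' Two-dimensional embedding of stressors
#'
#' t-distributed stochastic neighbor embedding run on the absolute values of
#' the correlation profiles (the clustering, by contrast, uses the raw signed
#' profiles). Deterministic given the seed.
#'
#' @param profiles correlation-profile matrix.
#' @param seed integer seed.
#' @param perplexity t-SNE perplexity (default 10, suited to the ~79-point
#'   stressor set).
#' @param n_iter gradient-descent iterations.
#' @return matrix (features x 2) of embedding coordinates.
#' @export
embed_psfs <- function(profiles, seed = 1L, perplexity = 10, n_iter = 400) {
  profiles <- as.matrix(profiles)
  stopifnot(nrow(profiles) >= 3)
  Y <- tsne_embed_matrix(abs(profiles),
    perplexity = perplexity,
    n_iter = n_iter, seed = seed
  )
  rownames(Y) <- rownames(profiles)
  colnames(Y) <- c("tsne1", "tsne2")
  Y
}

#' Associate stressors and stressor clusters with APORFs
#'
#' Per stressor x APORF pair: Spearman rho and p (pairwise-complete, t
#' approximation), significance at the unadjusted `p < alpha` (no multiple
#' testing correction is applied at this stage, deliberately). Cluster-level
#' summaries use the any-member rule: an APORF counts as associated with a
#' cluster if any member stressor is significantly associated with it; the
#' per-cluster per-APORF percentage is the share of significant member
#' stressors. Per-stressor counts are split into APO and risk-factor
#' tallies, and the rho heatmap is returned with non-significant cells
#' masked (`NA`).
#'
#' @param fm a `feature_matrix` of stressors.
#' @param outcomes aligned `cohort_table`.
#' @param clusters a `cluster_assignment` over the stressors of `fm`.
#' @param alpha unadjusted significance level.
#' @param tasks outcome columns to associate against (default the seven
#'   modelled APORFs).
#' @return object of class `association_result`: list with matrices `rho`,
#'   `p`, `significant`, the masked `rho_masked`, `alpha`,
#'   `cluster_summary` (per cluster: size, n_assoc_aporfs,
#'   pct_significant_per_aporf) and `psf_summary` (per stressor: n_apo,
#'   n_rf, n_total significant associations).
#' @export
associate <- function(fm, outcomes, clusters, alpha = 0.05, tasks = NULL) {
  stopifnot(inherits(clusters, "cluster_assignment"))
  X <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  nm <- if (inherits(fm, "feature_matrix")) fm$feature_names else colnames(X)
  if (is.null(tasks)) {
    tasks <- default_task_columns(outcomes)
  }
  stopifnot(nrow(outcomes) == nrow(X))
  p_mat <- rho <- matrix(
    NA_real_, length(nm), length(tasks),
    dimnames = list(nm, tasks)
  )
  for (i in seq_along(nm)) {
    for (t in tasks) {
      s <- spearman_cor(X[, i], as.numeric(outcomes[[t]]))
      rho[i, t] <- s$rho
      p_mat[i, t] <- s$p
    }
  }
  sig <- !is.na(p_mat) & p_mat < alpha
  rho_masked <- rho
  rho_masked[!sig] <- NA_real_

  cls <- attr(outcomes, "outcome_class")
  apo_tasks <- if (!is.null(cls)) tasks[cls[tasks] == "apo"] else character()
  rf_tasks <- if (!is.null(cls)) tasks[cls[tasks] == "rf"] else character()

  asg <- clusters$assignment
  stopifnot(all(nm %in% asg$feature))
  cl_of <- asg$cluster[match(nm, asg$feature)]
  cluster_ids <- sort(unique(asg$cluster))
  cluster_summary <- lapply(cluster_ids, function(cid) {
    members <- which(cl_of == cid)
    pct <- 100 * colMeans(sig[members, , drop = FALSE])
    list(
      cluster = cid,
      size = length(members),
      n_assoc_aporfs = sum(colSums(sig[members, , drop = FALSE]) > 0),
      pct_significant_per_aporf = pct
    )
  })
  psf_summary <- data.frame(
    feature = nm,
    cluster = cl_of,
    n_apo = if (length(apo_tasks)) {
      rowSums(sig[, apo_tasks, drop = FALSE])
    } else {
      rep(NA_integer_, length(nm))
    },
    n_rf = if (length(rf_tasks)) {
      rowSums(sig[, rf_tasks, drop = FALSE])
    } else {
      rep(NA_integer_, length(nm))
    },
    n_total = rowSums(sig),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      rho = rho, p = p_mat, significant = sig, rho_masked = rho_masked,
      alpha = alpha, cluster_summary = cluster_summary,
      psf_summary = psf_summary, tasks = tasks
    ),
    class = "association_result"
  )
}

#' Write cluster assignment and association matrices
#'
#' @param clusters a `cluster_assignment`.
#' @param assoc an `association_result`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_cluster_results <- function(clusters, assoc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    file.path(dir, "cluster_assignment.csv"),
    file.path(dir, "association_rho.csv"),
    file.path(dir, "association_p.csv"),
    file.path(dir, "association_significant.csv"),
    file.path(dir, "cluster_summary.json")
  )
  utils::write.csv(clusters$assignment, paths[1], row.names = FALSE)
  utils::write.csv(assoc$rho, paths[2])
  utils::write.csv(assoc$p, paths[3])
  utils::write.csv(assoc$significant, paths[4])
  jsonlite::write_json(assoc$cluster_summary, paths[5],
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}
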