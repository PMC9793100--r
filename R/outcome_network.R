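#' Pairwise outcome interrelatedness network
#'
#' Computes all pairwise Spearman correlations (pairwise-complete, t
#' approximation for p-values) between the modelled APORFs and categorizes
#' every edge by correlation strength. The default cut points follow a
#' common reading of the strength taxonomy for rank correlations:
#' `|rho| < 0.3` weak, `0.3 <= |rho| <= 0.6` moderate, `|rho| > 0.6` strong;
#' both thresholds are exposed.
#'
#' @param outcomes a `cohort_table` (or any `data.frame` containing the
#'   outcome columns).
#' @param tasks character names of the outcome columns to correlate; default
#'   the seven modelled APORFs of a `cohort_table`.
#' @param thresholds numeric `c(weak_upper, moderate_upper)` cut points on
#'   `|rho|`.
#' @return object of class `aporf_network`: list with `labels`, `rho`, `p`
#'   and `n_pairs` matrices, an `edges` data frame (pair, rho, p, n,
#'   category) and `node_roles` (apo/rf where known).
#' @export
build_outcome_network <- function(outcomes, tasks = NULL,
                                  thresholds = c(0.3, 0.6)) {
  if (is.null(tasks)) {
    tasks <- default_task_columns(outcomes)
  }
  stopifnot(length(tasks) >= 2, all(tasks %in% names(outcomes)))
  k <- length(tasks)
  rho <- p <- npairs <- matrix(NA_real_, k, k, dimnames = list(tasks, tasks))
  diag(rho) <- 1
  diag(p) <- 0
  edges <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      s <- spearman_cor(outcomes[[tasks[i]]], outcomes[[tasks[j]]])
      rho[i, j] <- rho[j, i] <- s$rho
      p[i, j] <- p[j, i] <- s$p
      npairs[i, j] <- npairs[j, i] <- s$n
      edges[[length(edges) + 1]] <- data.frame(
        a = tasks[i], b = tasks[j], rho = s$rho, p = s$p, n = s$n,
        category = edge_category(s$rho, thresholds),
        stringsAsFactors = FALSE
      )
    }
  }
  diag(npairs) <- vapply(tasks, function(t) sum(!is.na(outcomes[[t]])), 0)
  cls <- attr(outcomes, "outcome_class")
  roles <- if (is.null(cls)) {
    stats::setNames(rep(NA_character_, k), tasks)
  } else {
    stats::setNames(unname(cls[tasks]), tasks)
  }
  structure(
    list(
      labels = tasks, rho = rho, p = p, n_pairs = npairs,
      edges = do.call(rbind, edges), node_roles = roles,
      thresholds = thresholds
    ),
    class = "aporf_network"
  )
}

edge_category <- function(rho, thresholds = c(0.3, 0.6)) {
  if (is.na(rho)) {
    return("undefined")
  }
  a <- abs(rho)
  if (a < thresholds[1]) "weak" else if (a <= thresholds[2]) "moderate" else "strong"
}

# The seven modelled APORF columns of a cohort table (preterm is represented
# by the continuous gestational age at delivery).
default_task_columns <- function(outcomes) {
  cand <- c(
    "hypertension", "diabetes", "gestational_diabetes",
    "superimposed_preeclampsia", "severe_preeclampsia",
    "ga_delivery_weeks", "bmi_prepregnancy"
  )
  found <- intersect(cand, names(outcomes))
  if (length(found) < 2) {
    stop("could not locate APORF outcome columns; pass `tasks` explicitly")
  }
  found
}

#' The seven modelled prediction tasks of a cohort table
#'
#' @param outcomes a `cohort_table`.
#' @return named character vector mapping outcome column to task kind
#'   (`binary` or `numeric`).
#' @export
default_task_specs <- function(outcomes = NULL) {
  c(
    hypertension = "binary", diabetes = "binary",
    gestational_diabetes = "binary",
    superimposed_preeclampsia = "binary", severe_preeclampsia = "binary",
    ga_delivery_weeks = "numeric", bmi_prepregnancy = "numeric"
  )
}

#' Write an outcome network as matrix CSV plus an edge-list JSON
#'
#' @param net an `aporf_network`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_outcome_network <- function(net, dir) {
  stopifnot(inherits(net, "aporf_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rho_path <- file.path(dir, "outcome_correlations.csv")
  utils::write.csv(net$rho, rho_path)
  edge_path <- file.path(dir, "outcome_edges.json")
  jsonlite::write_json(
    list(
      nodes = lapply(net$labels, function(l) {
        list(id = l, role = unname(net$node_roles[[l]]))
      }),
      edges = net$edges,
      thresholds = net$thresholds
    ),
    edge_path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(rho_path, edge_path))
}
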