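#' Network configuration for the multitask / single-task models
#'
#' Mirrors the architecture and training protocol of the study this pipeline emulates: a feature
#' embedding layer, two shared fully connected hidden layers of 150 units,
#' one task-specific module of 150 units per outcome, batch normalization and
#' ReLU at every hidden layer, full-batch Adam for at most 35 epochs with
#' early stopping at patience 1, binary cross-entropy for binary heads and
#' (scaled) mean squared error for numeric heads. The learning rate is not
#' part of that protocol; with a batch size equal to the whole
#' training set the gradient is noiseless and the customary minibatch Adam
#' default (1e-3) cannot move the weights appreciably within 35 epochs (it
#' fails even the linearly separable sanity case), so the default step is
#' 1e-2; both are exposed.
#'
#' @param n_features number of input features.
#' @param task_specs named character vector mapping task name to kind
#'   (`"binary"` or `"numeric"`), e.g. [default_task_specs()].
#' @param hidden_units width of every hidden layer.
#' @param n_shared_layers number of shared hidden layers.
#' @param max_epochs training epoch cap.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param mse_scale weight of each numeric task's mean squared error in the
#'   total loss (numeric targets are standardized per training split, so 1
#'   keeps the losses commensurate).
#' @param learning_rate Adam step size.
#' @param validation_fraction fraction of the training split carved out to
#'   monitor early stopping.
#' @param seed integer seed controlling initialization and the validation
#'   carve-out.
#' @return object of class `network_config`.
#' @export
network_config <- function(n_features, task_specs,
                           hidden_units = 150, n_shared_layers = 2,
                           max_epochs = 35, patience = 1,
                           mse_scale = 1, learning_rate = 1e-2,
                           validation_fraction = 0.2, seed = 1L) {
  stopifnot(
    n_features >= 1, hidden_units > 0, n_shared_layers >= 1,
    length(task_specs) >= 1, !is.null(names(task_specs)),
    all(task_specs %in% c("binary", "numeric")),
    max_epochs >= 1, patience >= 1, mse_scale >= 0,
    learning_rate > 0, validation_fraction > 0, validation_fraction < 1
  )
  structure(
    list(
      n_features = as.integer(n_features),
      task_specs = task_specs,
      hidden_units = as.integer(hidden_units),
      n_shared_layers = as.integer(n_shared_layers),
      max_epochs = as.integer(max_epochs),
      patience = as.integer(patience),
      mse_scale = mse_scale,
      learning_rate = learning_rate,
      validation_fraction = validation_fraction,
      seed = as.integer(seed)
    ),
    class = "network_config"
  )
}

#' Build an (untrained) multitask or single-task network
#'
#' The single-task variant is architecturally identical to the multitask
#' network restricted to one task-specific module and head.
#'
#' @param cfg a [network_config()].
#' @param multitask build the multitask variant; if `FALSE`, `cfg` must
#'   declare exactly one task.
#' @return object of class `mt_network`.
#' @export
build_network <- function(cfg, multitask = TRUE) {
  stopifnot(inherits(cfg, "network_config"))
  if (!multitask && length(cfg$task_specs) != 1) {
    stop("single-task network requires exactly one task in cfg$task_specs")
  }
  set.seed(cfg$seed)
  net <- list(
    cfg = cfg,
    tasks = as.list(cfg$task_specs),
    multitask = multitask,
    params = NULL, bn = NULL, trained = FALSE
  )
  net$params <- mlp_init_params(cfg, net$tasks)
  net$bn <- mlp_init_bn(cfg, net$tasks)
  class(net) <- "mt_network"
  net
}

#' Number of trainable parameters of a network
#'
#' @param net an `mt_network`.
#' @return integer parameter count.
#' @export
n_params <- function(net) {
  stopifnot(inherits(net, "mt_network"))
  sum(unlist(rapply(net$params, length, how = "list")))
}

#' Train a network with full-batch Adam and early stopping
#'
#' Carves `cfg$validation_fraction` of the rows out as a validation slice,
#' performs one full-batch Adam step per epoch on the remainder, monitors the
#' total validation loss in evaluation mode, and returns the parameters of
#' the best-validation epoch once `cfg$patience` epochs pass without
#' improvement (or `cfg$max_epochs` is reached). Deterministic given
#' `cfg$seed`.
#'
#' @param net an `mt_network` from [build_network()].
#' @param X complete numeric feature matrix (no missing values; impute and
#'   scale upstream).
#' @param Y `data.frame` or named list with one column/element per task;
#'   binary targets in 0/1, numeric targets standardized.
#' @return the trained network, with `$history` (per-epoch train/validation
#'   loss), `$best_epoch` and `$n_epochs`.
#' @export
train_network <- function(net, X, Y) {
  stopifnot(inherits(net, "mt_network"))
  cfg <- net$cfg
  X <- as.matrix(X)
  if (anyNA(X)) {
    stop("X contains missing values; impute upstream")
  }
  Y <- lapply(as.list(Y)[names(net$tasks)], as.numeric)
  stopifnot(all(lengths(Y) == nrow(X)))
  set.seed(cfg$seed)
  n <- nrow(X)
  n_val <- max(1L, round(cfg$validation_fraction * n))
  val <- sample.int(n, n_val)
  tr <- setdiff(seq_len(n), val)
  Xtr <- X[tr, , drop = FALSE]
  Ytr <- lapply(Y, function(y) y[tr])
  Xval <- X[val, , drop = FALSE]
  Yval <- lapply(Y, function(y) y[val])

  m <- zero_like(net$params)
  v <- zero_like(net$params)
  best <- Inf
  best_epoch <- 0L
  bad <- 0L
  best_params <- net$params
  best_bn <- net$bn
  history <- data.frame(
    epoch = integer(), train_loss = numeric(), val_loss = numeric()
  )
  for (epoch in seq_len(cfg$max_epochs)) {
    gr <- mlp_grads(net, Xtr, Ytr)
    if (!is.finite(gr$loss)) {
      stop("divergent (non-finite) training loss at epoch ", epoch)
    }
    net$bn <- gr$bn
    st <- adam_step(net$params, gr$grads, m, v, cfg$learning_rate, epoch)
    net$params <- st$p
    m <- st$m
    v <- st$v
    val_fw <- mlp_forward(net, Xval, train = FALSE)
    val_loss <- mlp_loss(net, val_fw$scores, Yval)$total
    if (!is.finite(val_loss)) {
      stop("divergent (non-finite) validation loss at epoch ", epoch)
    }
    history[epoch, ] <- list(epoch, gr$loss, val_loss)
    if (val_loss < best) {
      best <- val_loss
      best_epoch <- epoch
      bad <- 0L
      best_params <- net$params
      best_bn <- net$bn
    } else {
      bad <- bad + 1L
      if (bad >= cfg$patience) break
    }
  }
  net$params <- best_params
  net$bn <- best_bn
  net$trained <- TRUE
  net$history <- history
  net$best_epoch <- best_epoch
  net$n_epochs <- nrow(history)
  net
}

#' Predict task scores from a trained network
#'
#' @param object a trained `mt_network`.
#' @param newdata numeric feature matrix.
#' @param ... unused.
#' @return named list of per-task score vectors (probabilities for binary
#'   tasks).
#' @export
predict.mt_network <- function(object, newdata, ...) {
  fw <- mlp_forward(object, as.matrix(newdata), train = FALSE)
  fw$scores
}

#' Repeated stratified K-fold evaluation of multitask vs single-task models
#'
#' For every repetition: draw a stratified K-fold split (stratified on the
#' composite any-positive-task indicator by default), train on each training
#' fold and collect held-out predictions over all folds, then compute one
#' metric per task per repetition from the pooled held-out predictions -
#' AUROC for binary tasks, Spearman rho for numeric tasks. Both model
#' classes are evaluated on identical splits. Features are standardized and
#' mean-imputed per fold using training-rows statistics only; numeric targets
#' are standardized per fold the same way.
#'
#' @param features a `feature_matrix` or plain numeric matrix (missing
#'   entries allowed; they are imputed per fold).
#' @param outcomes `data.frame` holding the task columns named in
#'   `cfg$task_specs`.
#' @param cfg a [network_config()].
#' @param k number of folds.
#' @param n_repetitions number of repeated splits.
#' @param model_classes which arms to run (`"multitask"`,
#'   `"singletask"` or both).
#' @param singletask_tasks tasks to fit in the single-task arm (default
#'   all); restricting this saves time when only some tasks are compared.
#' @param stratify_on column of `outcomes` to stratify folds on, or `"any"`
#'   for the composite indicator over binary tasks.
#' @return object of class `mt_evaluation`: list with `performance` (long
#'   data frame: task, model_class, metric, repetition, value),
#'   `predictions` (pooled held-out predictions) and `splits` (per
#'   repetition fold membership, shared between arms).
#' @export
evaluate_repeated_kfold <- function(features, outcomes, cfg, k = 5,
                                    n_repetitions = 20,
                                    model_classes = c("multitask", "singletask"),
                                    singletask_tasks = NULL,
                                    stratify_on = "any") {
  stopifnot(inherits(cfg, "network_config"))
  X <- if (inherits(features, "feature_matrix")) features$values else as.matrix(features)
  n <- nrow(X)
  stopifnot(nrow(outcomes) == n)
  tasks <- cfg$task_specs
  binary_tasks <- names(tasks)[tasks == "binary"]
  numeric_tasks <- names(tasks)[tasks == "numeric"]
  if (is.null(singletask_tasks)) singletask_tasks <- names(tasks)
  strat <- if (identical(stratify_on, "any")) {
    if (length(binary_tasks)) {
      as.integer(rowSums(as.matrix(outcomes[, binary_tasks, drop = FALSE])) > 0)
    } else {
      rep(0L, n)
    }
  } else {
    outcomes[[stratify_on]]
  }
  for (t in binary_tasks) {
    if (sum(outcomes[[t]] > 0) < k) {
      warning("task ", t, " has fewer than k positives; folds may be single-class")
    }
  }

  perf <- list()
  preds <- list()
  splits <- list()
  for (r in seq_len(n_repetitions)) {
    set.seed(cfg$seed + r)
    folds <- stratified_folds(strat, k)
    splits[[r]] <- folds
    scores <- list()
    for (mc in model_classes) {
      scores[[mc]] <- matrix(
        NA_real_, n, length(tasks),
        dimnames = list(NULL, names(tasks))
      )
    }
    truth_num <- matrix(
      NA_real_, n, length(numeric_tasks),
      dimnames = list(NULL, numeric_tasks)
    )
    for (f in seq_along(folds)) {
      test <- folds[[f]]
      train <- setdiff(seq_len(n), test)
      sc <- standardize_by_fit(X, fit = train)
      Xs <- sc$values
      Ytr <- list()
      for (t in names(tasks)) {
        y <- as.numeric(outcomes[[t]])
        if (tasks[[t]] == "numeric") {
          mu <- mean(y[train])
          s <- stats::sd(y[train])
          if (!is.finite(s) || s == 0) s <- 1
          y <- (y - mu) / s
          truth_num[test, t] <- y[test]
        }
        Ytr[[t]] <- y
      }
      fold_seed <- cfg$seed + 1000L * r + f
      if ("multitask" %in% model_classes) {
        mcfg <- cfg
        mcfg$seed <- fold_seed
        netm <- train_network(
          build_network(mcfg, multitask = TRUE),
          Xs[train, , drop = FALSE], lapply(Ytr, function(y) y[train])
        )
        pm <- predict(netm, Xs[test, , drop = FALSE])
        for (t in names(tasks)) scores[["multitask"]][test, t] <- pm[[t]]
      }
      if ("singletask" %in% model_classes) {
        for (t in singletask_tasks) {
          scfg <- cfg
          scfg$task_specs <- tasks[t]
          scfg$seed <- fold_seed
          nets <- train_network(
            build_network(scfg, multitask = FALSE),
            Xs[train, , drop = FALSE],
            lapply(Ytr[t], function(y) y[train])
          )
          ps <- predict(nets, Xs[test, , drop = FALSE])
          scores[["singletask"]][test, t] <- ps[[t]]
        }
      }
    }
    # metrics from pooled held-out predictions
    for (mc in model_classes) {
      run_tasks <- if (mc == "singletask") singletask_tasks else names(tasks)
      for (t in run_tasks) {
        s <- scores[[mc]][, t]
        if (anyNA(s)) next
        if (tasks[[t]] == "binary") {
          y <- as.numeric(outcomes[[t]])
          if (length(unique(y)) < 2) {
            warning("single-class truth for task ", t, "; metric skipped")
            next
          }
          value <- auroc(y, s)
          metric <- "auroc"
        } else {
          value <- spearman_cor(truth_num[, t], s)$rho
          metric <- "spearman_rho"
        }
        perf[[length(perf) + 1]] <- data.frame(
          task = t, model_class = mc, metric = metric,
          repetition = r, value = value, stringsAsFactors = FALSE
        )
      }
    }
  }
  structure(
    list(
      performance = do.call(rbind, perf),
      splits = splits
    ),
    class = "mt_evaluation"
  )
}

#' Extract the per-repetition metric samples for one task and model class
#'
#' @param eval an `mt_evaluation`.
#' @param task task name.
#' @param model_class `"multitask"` or `"singletask"`.
#' @return numeric vector ordered by repetition.
#' @export
perf_samples <- function(eval, task, model_class) {
  d <- eval$performance
  d <- d[d$task == task & d$model_class == model_class, ]
  d$value[order(d$repetition)]
}

#' Compare two performance distributions with the Wilcoxon test
#'
#' Paired (signed-rank, pairing repetitions that share splits) by default;
#' set `paired = FALSE` for the rank-sum variant. Identical samples yield
#' p = 1 and "ns".
#'
#' @param a,b numeric metric samples (equal length when paired).
#' @param paired use the signed-rank test.
#' @return list with `p` and `stars` (see [star_label()]).
#' @export
compare_models <- function(a, b, paired = TRUE) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (paired) {
    stopifnot(length(a) == length(b))
    if (all(a == b)) {
      return(list(p = 1, stars = "ns"))
    }
  }
  p <- suppressWarnings(stats::wilcox.test(a, b, paired = paired)$p.value)
  if (is.na(p)) p <- 1
  list(p = p, stars = star_label(p))
}

#' Per-task multitask vs single-task comparison table
#'
#' @param eval an `mt_evaluation` containing both model classes.
#' @param paired use the paired signed-rank variant.
#' @return data frame with per-task medians of both arms, the Wilcoxon p and
#'   the star label.
#' @export
comparison_table <- function(eval, paired = TRUE) {
  d <- eval$performance
  tasks <- intersect(
    unique(d$task[d$model_class == "multitask"]),
    unique(d$task[d$model_class == "singletask"])
  )
  rows <- lapply(tasks, function(t) {
    a <- perf_samples(eval, t, "multitask")
    b <- perf_samples(eval, t, "singletask")
    cmp <- compare_models(a, b, paired = paired)
    data.frame(
      task = t, metric = d$metric[d$task == t][1],
      median_multitask = stats::median(a), median_singletask = stats::median(b),
      p = cmp$p, stars = cmp$stars, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
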