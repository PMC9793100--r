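# Multitask feed-forward network in plain matrix code.
#
# Architecture: affine feature embedding -> n_shared_layers shared blocks
# (affine -> batch norm -> ReLU) -> one task-specific block per outcome
# (affine -> batch norm -> ReLU) -> per-task affine head (sigmoid for binary
# tasks, identity for numeric tasks). Batch normalization uses batch
# statistics during training and exponentially averaged running statistics
# for evaluation. Training is full-batch Adam on the summed loss
# (binary cross-entropy for binary heads, mse_scale * mean squared error for
# numeric heads) with early stopping on a held-out validation slice.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

add_rows <- function(M, b) sweep(M, 2, b, "+")
relu <- function(x) x * (x > 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

mlp_init_params <- function(cfg, tasks) {
  h <- cfg$hidden_units
  d <- cfg$n_features
  rn <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
  block <- function(fan_in) {
    list(
      W = rn(fan_in, h, sqrt(2 / fan_in)), b = numeric(h),
      g = rep(1, h), be = numeric(h)
    )
  }
  params <- list(
    emb = list(W = rn(d, h, sqrt(1 / d)), b = numeric(h)),
    shared = lapply(seq_len(cfg$n_shared_layers), function(i) block(h)),
    task = stats::setNames(lapply(tasks, function(t) {
      c(block(h), list(Wh = rn(h, 1, sqrt(1 / h)), bh = 0))
    }), names(tasks))
  )
  params
}

mlp_init_bn <- function(cfg, tasks) {
  h <- cfg$hidden_units
  one <- function() list(mean = numeric(h), var = rep(1, h))
  list(
    shared = lapply(seq_len(cfg$n_shared_layers), function(i) one()),
    task = stats::setNames(lapply(tasks, function(t) one()), names(tasks))
  )
}

bn_forward <- function(A, g, be, stats_ln, train) {
  if (train) {
    n <- nrow(A)
    mu <- colMeans(A)
    Ac <- add_rows(A, -mu)
    v <- colMeans(Ac^2)
    si <- 1 / sqrt(v + BN_EPS)
    Ah <- sweep(Ac, 2, si, "*")
    ub <- if (n > 1) v * n / (n - 1) else v
    new_stats <- list(
      mean = (1 - BN_MOMENTUM) * stats_ln$mean + BN_MOMENTUM * mu,
      var = (1 - BN_MOMENTUM) * stats_ln$var + BN_MOMENTUM * ub
    )
    list(
      Z = add_rows(sweep(Ah, 2, g, "*"), be),
      Ah = Ah, si = si, stats = new_stats
    )
  } else {
    si <- 1 / sqrt(stats_ln$var + BN_EPS)
    Ah <- sweep(add_rows(A, -stats_ln$mean), 2, si, "*")
    list(Z = add_rows(sweep(Ah, 2, g, "*"), be), Ah = Ah, si = si, stats = stats_ln)
  }
}

bn_backward <- function(dZ, Ah, si, g, train) {
  dg <- colSums(dZ * Ah)
  dbe <- colSums(dZ)
  dAh <- sweep(dZ, 2, g, "*")
  if (train) {
    n <- nrow(dZ)
    s1 <- colSums(dAh)
    s2 <- colSums(dAh * Ah)
    dA <- sweep(
      dAh - add_rows(Ah * 0, s1 / n) - sweep(Ah, 2, s2 / n, "*"),
      2, si, "*"
    )
  } else {
    dA <- sweep(dAh, 2, si, "*")
  }
  list(dA = dA, dg = dg, dbe = dbe)
}

# Forward pass; returns per-task scores plus caches when train = TRUE.
mlp_forward <- function(net, X, train = FALSE) {
  p <- net$params
  bn <- net$bn
  caches <- list(shared = list(), task = list())
  H <- add_rows(X %*% p$emb$W, p$emb$b)
  H_in <- list()
  for (l in seq_along(p$shared)) {
    H_in[[l]] <- H
    A <- add_rows(H %*% p$shared[[l]]$W, p$shared[[l]]$b)
    f <- bn_forward(A, p$shared[[l]]$g, p$shared[[l]]$be, bn$shared[[l]], train)
    bn$shared[[l]] <- f$stats
    Z <- f$Z
    H <- relu(Z)
    caches$shared[[l]] <- list(Ah = f$Ah, si = f$si, Z = Z, H_out = H)
  }
  scores <- list()
  for (t in names(p$task)) {
    pt <- p$task[[t]]
    A <- add_rows(H %*% pt$W, pt$b)
    f <- bn_forward(A, pt$g, pt$be, bn$task[[t]], train)
    bn$task[[t]] <- f$stats
    Z <- f$Z
    M <- relu(Z)
    s <- drop(M %*% pt$Wh) + pt$bh
    scores[[t]] <- if (net$tasks[[t]] == "binary") sigmoid(s) else s
    caches$task[[t]] <- list(Ah = f$Ah, si = f$si, Z = Z, M = M, raw = s)
  }
  list(
    scores = scores, trunk = H, trunk_inputs = H_in,
    caches = caches, bn = bn
  )
}

mlp_loss <- function(net, scores, Y) {
  total <- 0
  per_task <- numeric(0)
  for (t in names(net$tasks)) {
    y <- Y[[t]]
    s <- scores[[t]]
    if (net$tasks[[t]] == "binary") {
      pr <- pmin(pmax(s, 1e-7), 1 - 1e-7)
      lt <- -mean(y * log(pr) + (1 - y) * log(1 - pr))
    } else {
      lt <- net$cfg$mse_scale * mean((s - y)^2)
    }
    per_task[t] <- lt
    total <- total + lt
  }
  list(total = total, per_task = per_task)
}

# One full-batch forward/backward; returns loss, gradients, updated BN state.
mlp_grads <- function(net, X, Y) {
  fw <- mlp_forward(net, X, train = TRUE)
  p <- net$params
  n <- nrow(X)
  loss <- mlp_loss(net, fw$scores, Y)
  g <- list(
    emb = list(W = 0 * p$emb$W, b = 0 * p$emb$b),
    shared = lapply(p$shared, function(l) lapply(l, function(x) 0 * x)),
    task = lapply(p$task, function(l) lapply(l, function(x) 0 * x))
  )
  H <- fw$trunk
  dH <- matrix(0, nrow(H), ncol(H))
  for (t in names(p$task)) {
    pt <- p$task[[t]]
    ct <- fw$caches$task[[t]]
    y <- Y[[t]]
    if (net$tasks[[t]] == "binary") {
      ds <- (fw$scores[[t]] - y) / n
    } else {
      ds <- net$cfg$mse_scale * 2 * (fw$scores[[t]] - y) / n
    }
    g$task[[t]]$Wh <- crossprod(ct$M, ds)
    g$task[[t]]$bh <- sum(ds)
    dM <- outer(ds, drop(pt$Wh))
    dZ <- dM * (ct$Z > 0)
    bb <- bn_backward(dZ, ct$Ah, ct$si, pt$g, train = TRUE)
    g$task[[t]]$g <- bb$dg
    g$task[[t]]$be <- bb$dbe
    g$task[[t]]$W <- crossprod(H, bb$dA)
    g$task[[t]]$b <- colSums(bb$dA)
    dH <- dH + tcrossprod(bb$dA, pt$W)
  }
  for (l in rev(seq_along(p$shared))) {
    cl <- fw$caches$shared[[l]]
    dZ <- dH * (cl$Z > 0)
    bb <- bn_backward(dZ, cl$Ah, cl$si, p$shared[[l]]$g, train = TRUE)
    g$shared[[l]]$g <- bb$dg
    g$shared[[l]]$be <- bb$dbe
    g$shared[[l]]$W <- crossprod(fw$trunk_inputs[[l]], bb$dA)
    g$shared[[l]]$b <- colSums(bb$dA)
    dH <- tcrossprod(bb$dA, p$shared[[l]]$W)
  }
  g$emb$W <- crossprod(X, dH)
  g$emb$b <- colSums(dH)
  list(loss = loss$total, per_task = loss$per_task, grads = g, bn = fw$bn)
}

# Recursive Adam step over the nested parameter list.
adam_step <- function(params, grads, m, v, lr, t,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.list(params)) {
    out_p <- params
    out_m <- m
    out_v <- v
    for (k in seq_along(params)) {
      r <- adam_step(params[[k]], grads[[k]], m[[k]], v[[k]], lr, t, b1, b2, eps)
      out_p[[k]] <- r$p
      out_m[[k]] <- r$m
      out_v[[k]] <- r$v
    }
    return(list(p = out_p, m = out_m, v = out_v))
  }
  m <- b1 * m + (1 - b1) * grads
  v <- b2 * v + (1 - b2) * grads^2
  mh <- m / (1 - b1^t)
  vh <- v / (1 - b2^t)
  list(p = params - lr * mh / (sqrt(vh) + eps), m = m, v = v)
}

zero_like <- function(x) {
  if (is.list(x)) lapply(x, zero_like) else x * 0
}
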