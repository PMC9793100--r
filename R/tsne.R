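# Exact t-distributed stochastic neighbor embedding for small point sets.
#
# A plain implementation of the standard algorithm: per-point bandwidths
# found by binary search to match the target perplexity, symmetrized input
# affinities with early exaggeration, Student-t low-dimensional kernel, and
# momentum gradient descent. Exact O(n^2) gradients are entirely adequate at
# the scale used here (tens to a few hundred points).

tsne_embed_matrix <- function(X, perplexity = 10, n_iter = 400, seed = 1L,
                              lr = NULL) {
  n <- nrow(X)
  stopifnot(n >= 3)
  # step size scaled to the point count: large steps overshoot the strong
  # pairwise attractions of small point sets
  if (is.null(lr)) lr <- max(2, n / 12)
  perplexity <- min(perplexity, floor((n - 1) / 3))
  perplexity <- max(perplexity, 2)
  D2 <- as.matrix(stats::dist(X))^2
  P <- cond_probs(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  set.seed(as.integer(seed))
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  inc <- matrix(0, n, 2)
  momentum <- 0.5
  exaggeration <- 4
  for (it in seq_len(n_iter)) {
    if (it == 101) {
      exaggeration <- 1
      momentum <- 0.8
    }
    sum_y <- rowSums(Y^2)
    num <- 1 / (1 + outer(sum_y, sum_y, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (exaggeration * P - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    inc <- momentum * inc - lr * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

# Conditional affinities p_{j|i} at the bandwidth matching log-perplexity.
cond_probs <- function(D2, perplexity, tol = 1e-5, max_tries = 50) {
  n <- nrow(D2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1
    lo <- -Inf
    hi <- Inf
    di <- D2[i, -i]
    for (tr in seq_len(max_tries)) {
      ex <- exp(-di * beta)
      s <- sum(ex)
      if (s <= 0) {
        h <- 0
        pr <- rep(0, length(di))
        pr[which.min(di)] <- 1
      } else {
        pr <- ex / s
        h <- -sum(pr[pr > 0] * log(pr[pr > 0]))
      }
      diff <- h - target
      if (abs(diff) < tol) break
      if (diff > 0) {
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    P[i, -i] <- pr
  }
  P
}
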