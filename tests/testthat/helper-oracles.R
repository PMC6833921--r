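# Independent oracles used to check the implementation. Deliberately naive:
# double loops and textbook formulas, no shared code with the package.

# elementwise objective: 0.5 * sum of squared residuals by explicit loops
objective_oracle <- function(A, W, H) {
  n <- nrow(A); m <- ncol(A); r <- ncol(W)
  acc <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    pred <- 0
    for (k in seq_len(r)) pred <- pred + W[i, k] * H[k, j]
    acc <- acc + (A[i, j] - pred)^2
  }
  0.5 * acc
}

# central finite differences of a scalar function of a matrix
fd_grad <- function(f, X, h = 1e-6) {
  G <- X
  for (i in seq_along(X)) {
    Xp <- X; Xp[i] <- X[i] + h
    Xm <- X; Xm[i] <- X[i] - h
    G[i] <- (f(Xp) - f(Xm)) / (2 * h)
  }
  G
}

# projected-gradient residual by explicit per-entry case analysis
kkt_oracle <- function(A, W, H) {
  gw <- -A %*% t(H) + W %*% H %*% t(H)
  gh <- -t(W) %*% A + t(W) %*% W %*% H
  acc <- 0
  for (i in seq_along(W)) {
    v <- if (W[i] > 0) gw[i] else min(0, gw[i])
    acc <- acc + v^2
  }
  for (i in seq_along(H)) {
    v <- if (H[i] > 0) gh[i] else min(0, gh[i])
    acc <- acc + v^2
  }
  sqrt(acc)
}

# classical multiplicative-update NMF (baseline parity oracle)
mu_nmf <- function(A, W, H, iters = 500L, eps = 1e-12) {
  for (it in seq_len(iters)) {
    H <- H * crossprod(W, A) / pmax(crossprod(W) %*% H, eps)
    W <- W * tcrossprod(A, H) / pmax(W %*% tcrossprod(H), eps)
  }
  list(W = W, H = H)
}

# a tiny exactly factorizable instance: disjoint-support W*, one-hot H*
exact_planted_6x4 <- function() {
  W <- rbind(c(1.0, 0), c(0.8, 0), c(0.5, 0),
             c(0, 0.9), c(0, 0.7), c(0, 1.1))
  H <- rbind(c(1, 0, 1, 0),
             c(0, 1, 0, 1))
  list(A = W %*% H, W = W, H = H, labels = c(1L, 2L, 1L, 2L))
}
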