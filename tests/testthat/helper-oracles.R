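# Shared fixtures and independent oracles used across the suite.

# Random symmetric PSD matrix with O(1) entries.
random_psd <- function(n, seed) {
  set.seed(seed)
  A <- matrix(rnorm(n * (n + 2L)), n, n + 2L)
  tcrossprod(A) / (n + 2L)
}

random_labels <- function(n, seed) {
  set.seed(seed)
  y <- sign(rnorm(n))
  y[y == 0] <- 1
  if (all(y == y[1L])) y[1L] <- -y[1L]
  y
}

# Independent LSSVM oracle: assemble and solve the full (n+1)-dimensional
# saddle system [[0, 1'], [1, K + I/lam]] (b, alpha)' = (0, y)'.
lssvm_saddle_oracle <- function(K, y, lam) {
  n <- nrow(K)
  Kt <- K + diag(1 / lam, n)
  A <- rbind(c(0, rep(1, n)), cbind(rep(1, n), Kt))
  sol <- solve(A, c(0, y))
  list(bias = sol[1L], alpha = sol[-1L])
}

# Explicit style-transformation oracle for a raw linear kernel: builds the
# per-group d x d matrices A_j' = I + s * wbar %*% t(v_j) directly from the
# closed form and transforms the features themselves.
explicit_style_oracle <- function(X, alpha, group, lam, gamma) {
  s <- 1 / (2 * lam * gamma)
  wbar <- as.numeric(crossprod(X, alpha))
  d <- ncol(X)
  Xhat <- X
  for (g in unique(group)) {
    idx <- which(group == g)
    v <- as.numeric(crossprod(X[idx, , drop = FALSE], alpha[idx]))
    At <- diag(d) + s * outer(wbar, v)       # A_g'
    Xhat[idx, ] <- X[idx, , drop = FALSE] %*% t(At)  # rows become A_g' x
  }
  list(gram = tcrossprod(Xhat), Xhat = Xhat, wbar = wbar)
}

# Independent quadratic-programming oracle for the per-group style
# subproblem with the classifier (wbar, b) held fixed: eliminate the
# residuals and solve the normal equations of the resulting ridge problem
# in vec(A') directly.
style_qp_oracle <- function(X, y, wbar, b, lam, gamma) {
  d <- ncol(X)
  Mk <- t(apply(X, 1L, function(x) as.numeric(outer(wbar, x))))  # vec(wbar x')
  i0 <- as.numeric(diag(d))
  lhs <- crossprod(Mk) + diag(2 * gamma, d * d)
  rhs <- as.numeric(crossprod(Mk, y - b)) + 2 * gamma * i0
  matrix(solve(lhs, rhs), d, d)  # A'
}

# Small well-separated style-grouped dataset for exact-recovery checks.
separable_dataset <- function(seed = 1L, n_groups = 3L, per_group = 16L,
                              sep = 8) {
  generate_styled_data(synth_config(n_groups = n_groups,
                                    per_group = per_group, dim = 4L,
                                    class_sep = sep, style_strength = 0.3,
                                    noise_sd = 0.6, seed = seed))
}
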