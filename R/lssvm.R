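#' Solve the least-squares SVM dual system
#'
#' For a fixed Gram matrix `K`, labels `y` in \{+1, -1\} and ridge parameter
#' `lam`, solves the LSSVM dual: with \eqn{\tilde K = K + I/\lambda},
#' \deqn{b = \frac{1^T \tilde K^{-1} Y}{1^T \tilde K^{-1} 1}, \qquad
#'       \alpha = \tilde K^{-1} (Y - b 1).}
#' The solution satisfies the equality-constraint condition
#' \eqn{\sum_j \alpha_j = 0} and the KKT residual identity
#' \eqn{y_j - (K\alpha + b)_j = \alpha_j / \lambda}.
#'
#' @param K Symmetric PSD `n x n` Gram matrix.
#' @param y Numeric label vector in \{+1, -1\}.
#' @param lam Positive regularization parameter \eqn{\lambda}.
#' @return Object of class `"lssvm_dual"`: `alpha`, `bias`, `lam`.
#' @examples
#' sol <- solve_lssvm_dual(diag(2), c(1, -1), 1)
#' sol$alpha  # c(0.5, -0.5)
#' @export
solve_lssvm_dual <- function(K, y, lam) {
  if (!is.matrix(K) || nrow(K) != ncol(K)) {
    stop("'K' must be a square matrix", call. = FALSE)
  }
  n <- nrow(K)
  y <- as.numeric(y)
  if (length(y) != n) stop("length of 'y' must match 'K'", call. = FALSE)
  if (!all(y %in% c(-1, 1))) stop("labels must be +1 or -1", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  if (!is.numeric(lam) || length(lam) != 1L || lam <= 0) {
    stop("'lam' must be a positive real", call. = FALSE)
  }
  Kt <- K + diag(1 / lam, n)
  ch <- tryCatch(chol(Kt), error = function(e) NULL)
  if (is.null(ch)) {
    # PSD grams can be numerically semidefinite; retry with tiny jitter
    Kt <- Kt + diag(1e-10 * sum(diag(K)) / n, n)
    ch <- tryCatch(chol(Kt), error = function(e) {
      stop("Gram system is numerically singular", call. = FALSE)
    })
  }
  rhs <- cbind(y, rep(1, n))
  sol2 <- backsolve(ch, forwardsolve(t(ch), rhs))
  b <- sum(sol2[, 2L] * y) / sum(sol2[, 2L])
  alpha <- sol2[, 1L] - b * sol2[, 2L]
  structure(list(alpha = as.numeric(alpha), bias = as.numeric(b),
                 lam = lam),
            class = "lssvm_dual")
}

#' Decision values of an LSSVM dual solution
#'
#' Returns `K_cross %*% alpha + bias`, the real-valued decision function
#' evaluated through an `m x n` cross-kernel block (columns indexed by the
#' training samples).
#'
#' @param K_cross `m x n` matrix of kernel values between `m` evaluation
#'   points (rows) and the `n` training samples (columns).
#' @param sol An `"lssvm_dual"` solution.
#' @return Numeric vector of length `m`.
#' @export
decision_values <- function(K_cross, sol) {
  stopifnot(inherits(sol, "lssvm_dual"))
  if (!is.matrix(K_cross)) K_cross <- matrix(K_cross, nrow = 1L)
  if (ncol(K_cross) != length(sol$alpha)) {
    stop("'K_cross' must have one column per training sample", call. = FALSE)
  }
  as.numeric(K_cross %*% sol$alpha + sol$bias)
}

# sign with the fixed convention sign(0) = +1, so predictions are
# deterministic at decision value zero
sign_pos <- function(x) ifelse(x >= 0, 1, -1)
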