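#' Multi-kernel LSSVM via semi-infinite linear programming
#'
#' Learns simplex weights \eqn{\mu} over the base Gram matrices jointly with
#' the LSSVM dual variables by the standard cutting-plane (column generation)
#' scheme for the SILP reformulation of the min--max multi-kernel objective
#' \deqn{\min_{\mu \in \Delta} \max_{\alpha: \alpha^T 1 = 0}
#'  -\tfrac12 \sum_i \mu_i \alpha^T K_i \alpha
#'  - \tfrac{1}{2\lambda}\alpha^T\alpha + \alpha^T Y.}
#' Each outer iteration solves the LSSVM dual at the current \eqn{\mu}
#' (generating one linear cut in \eqn{\mu}) and then a small LP over
#' \eqn{(\mu, t)} with all cuts accumulated so far.
#'
#' @param stack A [gram_stack()].
#' @param y Labels in \{+1, -1\}.
#' @param lam Positive regularization parameter.
#' @param tol Relative-change tolerance on the incumbent SILP objective.
#' @param max_iter Maximum number of cutting-plane iterations.
#' @return Object of class `"mkl_model"` with elements `weights`
#'   ([kernel_weights()]), `dual` (the [solve_lssvm_dual()] solution at the
#'   returned weights), `stack` (the training Gram stack), `lam`,
#'   `objective_trace` (incumbent SILP objective per iteration,
#'   non-increasing by construction), `converged`, `n_iter`.
#' @seealso [predict_mkl()]
#' @export
fit_mkl <- function(stack, y, lam, tol = 1e-4, max_iter = 100L) {
  stopifnot(inherits(stack, "gram_stack"))
  if (!is.numeric(tol) || tol <= 0) stop("'tol' must be positive", call. = FALSE)
  M <- stack$M
  mu <- rep(1 / M, M)
  cuts_c <- matrix(numeric(0), nrow = 0L, ncol = M)
  cuts_d <- numeric(0)
  best <- NULL
  trace <- numeric(0)
  raw <- numeric(0)
  converged <- FALSE
  r <- 0L
  while (r < max_iter) {
    r <- r + 1L
    K <- combine_gram(stack, kernel_weights(mu))
    sol <- solve_lssvm_dual(K, y, lam)
    a <- sol$alpha
    cvec <- vapply(stack$grams, function(Ki) {
      -0.5 * sum(a * (Ki %*% a))
    }, numeric(1))
    dval <- -sum(a^2) / (2 * lam) + sum(a * y)
    f <- sum(mu * cvec) + dval
    raw[r] <- f
    if (is.null(best) || f < best$f) {
      best <- list(mu = mu, sol = sol, f = f)
    }
    trace[r] <- best$f
    if (M == 1L) { converged <- TRUE; break }
    cuts_c <- rbind(cuts_c, cvec)
    cuts_d <- c(cuts_d, dval)
    lp <- silp_lp(cuts_c, cuts_d)
    if (is.null(lp)) break  # LP backend failure: keep incumbent, flag below
    gap <- best$f - lp$t
    if (gap <= tol * max(abs(best$f), 1e-12)) { converged <- TRUE; break }
    if (r >= 2L &&
        abs(trace[r - 1L] - trace[r]) <= tol * max(abs(trace[r - 1L]), 1e-12)) {
      converged <- TRUE
      break
    }
    mu <- lp$mu
  }
  if (!converged) {
    warning("SILP cutting-plane loop did not converge within 'max_iter'",
            call. = FALSE)
  }
  structure(list(weights = kernel_weights(best$mu), dual = best$sol,
                 stack = stack, lam = lam, objective_trace = trace,
                 raw_objective = raw, converged = converged, n_iter = r),
            class = "mkl_model")
}

# Restricted master LP of the cutting-plane scheme:
#   min_{mu in simplex, t}  t   s.t.  t >= mu . c_r + d_r  for every cut r.
# Shifted so the epigraph variable is non-negative, then solved with
# pracma::linprog.  Returns NULL if the LP backend fails.
silp_lp <- function(cuts_c, cuts_d) {
  M <- ncol(cuts_c)
  R <- nrow(cuts_c)
  T0 <- max(abs(cuts_d)) + max(abs(cuts_c)) + 1
  # variables x = (mu_1..mu_M, tp) with t = tp - T0
  A <- cbind(cuts_c, -1)           # mu.c - tp <= -d - T0
  b <- -(cuts_d + T0)
  Aeq <- matrix(c(rep(1, M), 0), nrow = 1L)
  # the backend breaks degenerate pivot ties by sampling; pin the RNG (and
  # restore the caller's state) so training is bit-reproducible
  res <- tryCatch(
    with_seed(0L,
      pracma::linprog(cc = c(rep(0, M), 1), A = A, b = b,
                      Aeq = Aeq, beq = 1, maxiter = 200L + 10L * R,
                      maximize = FALSE)),
    error = function(e) NULL)
  if (is.null(res) || any(!is.finite(res$x))) return(NULL)
  mu <- pmax(res$x[seq_len(M)], 0)
  s <- sum(mu)
  if (s <= 0) return(NULL)
  list(mu = mu / s, t = res$x[M + 1L] - T0)
}

# Value of the dual (SILP) objective at weights mu for a given dual solve.
mkl_dual_objective <- function(stack, mu, sol, y) {
  a <- sol$alpha
  sum(vapply(seq_len(stack$M), function(i) {
    -0.5 * mu[i] * sum(a * (stack$grams[[i]] %*% a))
  }, numeric(1))) - sum(a^2) / (2 * sol$lam) + sum(a * y)
}

#' Predict with a multi-kernel LSSVM model
#'
#' Labels a new sample by the sign of
#' \eqn{\sum_j \alpha_j \sum_i \mu_i k_i(x_j, x) + b}
#' (with the convention sign(0) = +1).
#'
#' @param model An `"mkl_model"` from [fit_mkl()].
#' @param X_new `m x d` matrix of samples to label.
#' @param X_train The `n x d` training sample matrix the model was fit on.
#' @return Numeric vector of labels in \{+1, -1\}.
#' @export
predict_mkl <- function(model, X_new, X_train) {
  stopifnot(inherits(model, "mkl_model"))
  sign_pos(decision_values_mkl(model, X_new, X_train))
}

decision_values_mkl <- function(model, X_new, X_train) {
  Kc <- cross_combined(model$stack$specs, unclass(model$weights),
                       X_train, X_new, model$stack$normalize)
  decision_values(t(Kc), model$dual)
}

#' @export
print.mkl_model <- function(x, ...) {
  cat(sprintf("<mkl_model> %d kernels, n = %d, lambda = %g\n",
              x$stack$M, x$stack$n, x$lam))
  cat("  weights:", paste(sprintf("%.4f", unclass(x$weights)), collapse = " "),
      "\n")
  cat(sprintf("  SILP objective %.6g after %d iteration(s)%s\n",
              utils::tail(x$objective_trace, 1L), x$n_iter,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}
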