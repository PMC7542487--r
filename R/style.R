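#' Style-grouped binary-classification dataset
#'
#' The universal input container: feature rows, labels in \{+1, -1\}, and a
#' per-sample style-group id.  Samples sharing a group id are assumed to
#' carry one common systematic distortion ("style").
#'
#' @param X `n x d` numeric feature matrix.
#' @param y Labels in \{+1, -1\}.
#' @param group Integer style-group ids, one per sample.
#' @return Object of class `"style_dataset"`: `X`, `y`, `group`,
#'   `group_sizes` (named table).
#' @export
style_dataset <- function(X, y, group) {
  X <- check_features(X)
  dimnames(X) <- NULL
  y <- as.numeric(y)
  group <- as.integer(group)
  n <- nrow(X)
  if (n == 0L || ncol(X) == 0L) stop("empty dataset", call. = FALSE)
  if (length(y) != n || length(group) != n) {
    stop("'y' and 'group' must have one entry per row of 'X'", call. = FALSE)
  }
  if (!all(y %in% c(-1, 1))) stop("labels must be +1 or -1", call. = FALSE)
  if (anyNA(group) || any(group < 1L)) {
    stop("group ids must be positive integers", call. = FALSE)
  }
  structure(list(X = X, y = y, group = group,
                 group_sizes = table(group)),
            class = "style_dataset")
}

#' @export
print.style_dataset <- function(x, ...) {
  cat(sprintf("<style_dataset> %d samples, %d features, %d style group(s)\n",
              nrow(x$X), ncol(x$X), length(x$group_sizes)))
  cat("  group sizes:", paste(sprintf("%s:%d", names(x$group_sizes),
                                      as.integer(x$group_sizes)),
                              collapse = " "), "\n")
  invisible(x)
}

#' Initialize the per-group style model
#'
#' The style transformation of every group starts at the identity map: the
#' dual-coefficient snapshot is all zeros, so the closed-form update leaves
#' \eqn{A_j = I} and the transformed Gram equals the untransformed one.
#'
#' @param dataset A [style_dataset()].
#' @param lam Positive regularization parameter \eqn{\lambda} shared with the
#'   classifier.
#' @param gamma Positive style-regularization strength \eqn{\gamma}: larger
#'   values pin every \eqn{A_j} closer to the identity, and
#'   \eqn{\gamma \to \infty} recovers the style-free model.
#' @return Object of class `"style_model"`: `alpha_snapshot`, `lam`, `gamma`,
#'   `scale` = \eqn{1/(2\lambda\gamma)}, `group`, `weights` (kernel weights
#'   at snapshot time, `NULL` at initialization).
#' @export
init_style <- function(dataset, lam, gamma) {
  stopifnot(inherits(dataset, "style_dataset"))
  if (!is.numeric(lam) || length(lam) != 1L || lam <= 0) {
    stop("'lam' must be a positive real", call. = FALSE)
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0) {
    stop("'gamma' must be a positive real", call. = FALSE)
  }
  new_style_model(rep(0, nrow(dataset$X)), lam, gamma, dataset$group,
                  weights = NULL)
}

new_style_model <- function(alpha, lam, gamma, group, weights = NULL) {
  structure(list(alpha_snapshot = as.numeric(alpha), lam = lam, gamma = gamma,
                 scale = 1 / (2 * lam * gamma), group = as.integer(group),
                 weights = weights),
            class = "style_model")
}

#' Snapshot the style transformation from the current dual solve
#'
#' Stores the dual coefficients \eqn{\alpha} and \eqn{(\lambda, \gamma)}
#' that define every group's transformation implicitly through the
#' closed-form stationarity update
#' \deqn{A_j^T = \frac{1}{2\lambda\gamma}
#'   \sum_{k \in j} \alpha_j^k \, \bar w \, \Phi^T(x_j^k) + I,}
#' where \eqn{\bar w = \sum_m \alpha_m \Phi(x_m)} is the (implicit) primal
#' weight vector in the combined feature space.  No linear algebra happens
#' here; all computation is deferred to [transformed_gram()].
#'
#' @param dataset A [style_dataset()].
#' @param current_dual The `"lssvm_dual"` solution on the current transformed
#'   Gram.
#' @param weights Kernel weights in force at snapshot time.
#' @param gamma Positive style-regularization strength.
#' @return A `"style_model"`.
#' @export
update_style <- function(dataset, current_dual, weights, gamma) {
  stopifnot(inherits(dataset, "style_dataset"),
            inherits(current_dual, "lssvm_dual"))
  if (length(current_dual$alpha) != length(dataset$group)) {
    stop("dual coefficients and group ids have inconsistent lengths",
         call. = FALSE)
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0) {
    stop("'gamma' must be a positive real", call. = FALSE)
  }
  new_style_model(current_dual$alpha, current_dual$lam, gamma, dataset$group,
                  weights = if (is.null(weights)) NULL
                            else kernel_weights(unclass(weights)))
}

# Per-row helper quantities of the style expansion, computed from a combined
# base gram K (n_tot x n_tot), a snapshot alpha zero-padded to n_tot, and
# group ids of every row:
#   P[u] = sum_m alpha_m K[u, m]                    (Phi_u . w_bar)
#   C[u] = sum_{m in group(u)} alpha_m K[u, m]      (Phi_u . v_{group(u)})
#   rho  = alpha' K alpha                           (|w_bar|^2)
style_parts <- function(alpha, K, group) {
  P <- as.numeric(K %*% alpha)
  C <- numeric(length(P))
  for (g in unique(group)) {
    idx <- which(group == g)
    ag <- alpha
    ag[group != g] <- 0
    C[idx] <- as.numeric(K[idx, , drop = FALSE] %*% ag)
  }
  list(P = P, C = C, rho = sum(alpha * P))
}

#' Style-transformed combined Gram matrix
#'
#' Applies the implicit per-group affine maps to a combined Gram matrix using
#' only its entries (the kernel trick; no feature map is ever materialized).
#' With \eqn{s = 1/(2\lambda\gamma)}, snapshot coefficients \eqn{\alpha},
#' \eqn{P = K\alpha}, the group-restricted sums \eqn{c_u = \sum_{k \in
#' \mathrm{group}(u)} \alpha_k K_{uk}} and \eqn{\rho = \alpha^T K \alpha},
#' the transformed entry is the four-term expansion
#' \deqn{\hat K_{uv} = K_{uv} + s (P_u c_v + c_u P_v) + s^2 \rho \, c_u c_v.}
#'
#' Rows beyond the training samples (e.g. prediction samples appended to the
#' Gram) are supported by passing `group` ids for every row; appended rows
#' carry zero snapshot coefficients and simply inherit the transformation of
#' their declared group.
#'
#' @param model A `"style_model"`.
#' @param base_gram The \eqn{\mu}-combined Gram on the training set
#'   (optionally extended with appended prediction rows).
#' @param group Style-group id for every row of `base_gram`; defaults to the
#'   training groups stored in the model.
#' @return A matrix of the same shape as `base_gram`.
#' @export
transformed_gram <- function(model, base_gram, group = model$group) {
  stopifnot(inherits(model, "style_model"))
  if (!is.matrix(base_gram) || nrow(base_gram) != ncol(base_gram)) {
    stop("'base_gram' must be a square matrix", call. = FALSE)
  }
  n_tot <- nrow(base_gram)
  n <- length(model$alpha_snapshot)
  if (length(group) != n_tot || n_tot < n) {
    stop("'group' must label every row of 'base_gram'", call. = FALSE)
  }
  if (!all(model$group == group[seq_len(n)])) {
    stop("leading rows of 'base_gram' must be the training samples in order",
         call. = FALSE)
  }
  alpha <- c(model$alpha_snapshot, rep(0, n_tot - n))
  if (all(alpha == 0)) return(base_gram)
  sp <- style_parts(alpha, base_gram, group)
  s <- model$scale
  base_gram + s * (outer(sp$P, sp$C) + outer(sp$C, sp$P)) +
    s^2 * sp$rho * outer(sp$C, sp$C)
}

#' Frobenius style penalty
#'
#' Evaluates \eqn{\sum_j \|A_j^T - I\|_F^2} in kernel form: since
#' \eqn{A_j^T - I = s \bar w v_j^T} is rank one,
#' \eqn{\|A_j^T - I\|_F^2 = s^2 \, \|\bar w\|^2 \|v_j\|^2} with
#' \eqn{\|\bar w\|^2 = \alpha^T K \alpha} and
#' \eqn{\|v_j\|^2 = \sum_{k, k' \in j} \alpha_k \alpha_{k'} K_{kk'}}.
#'
#' @param model A `"style_model"`.
#' @param base_gram The combined training Gram the snapshot refers to.
#' @return A non-negative scalar.
#' @export
style_penalty <- function(model, base_gram) {
  stopifnot(inherits(model, "style_model"))
  alpha <- model$alpha_snapshot
  n <- length(alpha)
  if (!is.matrix(base_gram) || nrow(base_gram) != n || ncol(base_gram) != n) {
    stop("'base_gram' shape does not match the snapshot", call. = FALSE)
  }
  if (all(alpha == 0)) return(0)
  rho <- sum(alpha * (base_gram %*% alpha))
  v2 <- vapply(unique(model$group), function(g) {
    idx <- which(model$group == g)
    ag <- alpha[idx]
    sum(ag * (base_gram[idx, idx, drop = FALSE] %*% ag))
  }, numeric(1))
  max(model$scale^2 * rho * sum(v2), 0)
}

#' Materialize the style matrices for a linear kernel (test oracle)
#'
#' Only for a purely linear kernel bank is the feature map the identity, so
#' the per-group transformation can be written out as an explicit `d x d`
#' matrix
#' \eqn{A_j^T = I + \frac{1}{2\lambda\gamma} \sum_{k \in j} \alpha_j^k
#' \bar w \, x_j^{kT}} with \eqn{\bar w = \sum_m \alpha_m x_m}.
#' This exists to cross-check the implicit kernel-trick computation; it is
#' not part of the training path.
#'
#' @param model A `"style_model"`.
#' @param dataset The training [style_dataset()].
#' @param specs The kernel bank in force; every spec must be linear (any
#'   other family has no identity feature map and raises an error).  Gram
#'   normalization must also be off for the materialization to be exact.
#' @param w_bar Optional explicit primal weight vector; defaults to
#'   `colSums(alpha * X)`, the linear-kernel primal weight of the snapshot.
#' @return Named list of `d x d` matrices \eqn{A_j^T}, one per group id.
#' @export
materialize_A_linear <- function(model, dataset,
                                 specs = list(kernel_spec("linear")),
                                 w_bar = NULL) {
  stopifnot(inherits(model, "style_model"), inherits(dataset, "style_dataset"))
  fams <- vapply(specs, function(sp) sp$family, character(1))
  if (any(fams != "linear")) {
    stop("materialize_A_linear supports only a linear kernel bank",
         call. = FALSE)
  }
  alpha <- model$alpha_snapshot
  X <- dataset$X
  d <- ncol(X)
  if (is.null(w_bar)) w_bar <- as.numeric(crossprod(X, alpha))
  groups <- sort(unique(model$group))
  out <- lapply(groups, function(g) {
    idx <- which(model$group == g)
    v_g <- as.numeric(crossprod(X[idx, , drop = FALSE], alpha[idx]))
    diag(d) + model$scale * outer(w_bar, v_g)
  })
  names(out) <- as.character(groups)
  out
}
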