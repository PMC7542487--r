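#' Base kernel specification
#'
#' Describes one base kernel of the multi-kernel bank.  Three families are
#' supported: `linear` (\eqn{x^T z}), `polynomial` (\eqn{(x^T z + c_0)^p}),
#' and `gaussian` (\eqn{\exp(-\|x-z\|^2 / (2 w^2))} with bandwidth `width`).
#'
#' @param family One of `"linear"`, `"polynomial"`, `"gaussian"`.
#' @param degree Positive integer degree (polynomial only).
#' @param width Positive bandwidth (gaussian only).
#' @param coef0 Offset of the polynomial kernel; must be non-negative so the
#'   kernel stays positive semidefinite.
#' @return An object of class `"kernel_spec"`.
#' @examples
#' kernel_spec("gaussian", width = 1.5)
#' kernel_spec("polynomial", degree = 2, coef0 = 1)
#' @export
kernel_spec <- function(family = c("linear", "polynomial", "gaussian"),
                        degree = 2L, width = 1, coef0 = 1) {
  family <- match.arg(family)
  if (family == "polynomial") {
    if (!is.numeric(degree) || length(degree) != 1L || degree < 1 ||
        degree != round(degree)) {
      stop("'degree' must be a positive integer", call. = FALSE)
    }
    if (!is.numeric(coef0) || length(coef0) != 1L || coef0 < 0 ||
        !is.finite(coef0)) {
      stop("'coef0' must be a non-negative real", call. = FALSE)
    }
  }
  if (family == "gaussian") {
    if (!is.numeric(width) || length(width) != 1L || !is.finite(width) ||
        width <= 0) {
      stop("'width' must be a positive real", call. = FALSE)
    }
  }
  structure(
    list(family = family,
         degree = if (family == "polynomial") as.integer(degree) else NULL,
         width = if (family == "gaussian") as.numeric(width) else NULL,
         coef0 = if (family == "polynomial") as.numeric(coef0) else NULL),
    class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  extra <- switch(x$family,
    linear = "",
    polynomial = sprintf(" (degree = %d, coef0 = %g)", x$degree, x$coef0),
    gaussian = sprintf(" (width = %g)", x$width))
  cat("<kernel_spec> ", x$family, extra, "\n", sep = "")
  invisible(x)
}

check_features <- function(X, name = "X") {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (!is.numeric(X)) stop(sprintf("'%s' must be numeric", name), call. = FALSE)
  if (any(!is.finite(X))) {
    stop(sprintf("'%s' contains non-finite feature values", name), call. = FALSE)
  }
  X
}

#' Compute a Gram (kernel) matrix between two sample sets
#'
#' Entry \eqn{(p, q)} is \eqn{k(x_p, z_q)} for the given kernel spec.
#'
#' @param spec A [kernel_spec()].
#' @param X An `n x d` numeric matrix of samples (rows).
#' @param Z An `m x d` numeric matrix; defaults to `X`.
#' @return An `n x m` numeric matrix.
#' @examples
#' compute_gram(kernel_spec("linear"), diag(2))
#' @export
compute_gram <- function(spec, X, Z = X) {
  stopifnot(inherits(spec, "kernel_spec"))
  X <- check_features(X, "X")
  Z <- check_features(Z, "Z")
  if (ncol(X) != ncol(Z)) {
    stop("'X' and 'Z' must have the same number of columns", call. = FALSE)
  }
  G <- switch(spec$family,
    linear = tcrossprod(X, Z),
    polynomial = (tcrossprod(X, Z) + spec$coef0)^spec$degree,
    gaussian = {
      d2 <- outer(rowSums(X^2), rowSums(Z^2), "+") - 2 * tcrossprod(X, Z)
      d2[d2 < 0] <- 0
      exp(-d2 / (2 * spec$width^2))
    })
  # exact symmetry when the two sample sets are the same object
  if (nrow(G) == ncol(G) && identical(dim(X), dim(Z)) && all(X == Z)) {
    G <- (G + t(G)) / 2
  }
  unname(G)
}

# self-kernel values k(x, x), needed for cross normalization
gram_diag <- function(spec, X) {
  X <- check_features(X)
  switch(spec$family,
    linear = rowSums(X^2),
    polynomial = (rowSums(X^2) + spec$coef0)^spec$degree,
    gaussian = rep(1, nrow(X)))
}

#' Median pairwise distance heuristic
#'
#' The classic bandwidth heuristic for gaussian kernels: the median of all
#' pairwise Euclidean distances between rows of `X`.
#'
#' @param X Numeric sample matrix.
#' @return A positive scalar.
#' @export
median_heuristic <- function(X) {
  X <- check_features(X)
  m <- stats::median(stats::dist(X))
  if (!is.finite(m) || m <= 0) m <- 1
  m
}

#' Default multi-kernel bank
#'
#' Builds the conventional MKL bank: gaussian kernels at bandwidths
#' `median_heuristic(X) * 2^(-3:3)`, a linear kernel, and polynomial kernels
#' of degree 2 and 3 (10 kernels in total).
#'
#' @param X Sample matrix used for the median-distance heuristic.
#' @return A list of [kernel_spec()] objects.
#' @export
default_kernel_bank <- function(X) {
  med <- median_heuristic(X)
  c(lapply(med * 2^(-3:3), function(w) kernel_spec("gaussian", width = w)),
    list(kernel_spec("linear"),
         kernel_spec("polynomial", degree = 2, coef0 = 1),
         kernel_spec("polynomial", degree = 3, coef0 = 1)))
}

#' Unit-diagonal (cosine) normalization of a Gram matrix
#'
#' Rescales `K` to `K[p, q] / sqrt(K[p, p] * K[q, q])`, making heterogeneous
#' base kernels commensurable before they enter the weight optimization.
#'
#' @param K A symmetric PSD matrix with strictly positive diagonal.
#' @return A matrix with unit diagonal.
#' @export
normalize_gram <- function(K) {
  d <- diag(K)
  if (any(d <= 0)) {
    stop("degenerate kernel: zero or negative diagonal entry", call. = FALSE)
  }
  s <- 1 / sqrt(d)
  Kn <- K * tcrossprod(s)
  diag(Kn) <- 1
  Kn
}

normalize_cross <- function(Kc, diag_x, diag_z) {
  if (any(diag_x <= 0) || any(diag_z <= 0)) {
    stop("degenerate kernel: zero or negative self-kernel value", call. = FALSE)
  }
  Kc * tcrossprod(1 / sqrt(diag_x), 1 / sqrt(diag_z))
}

#' Stack of base Gram matrices
#'
#' Computes the `M` base Gram matrices of a kernel bank on one sample set.
#' With `normalize = TRUE` (the default) every base Gram is brought to unit
#' diagonal first, so kernels of different families live on one scale.
#'
#' @param X `n x d` sample matrix.
#' @param specs List of [kernel_spec()]; defaults to [default_kernel_bank()].
#' @param normalize Unit-diagonal normalize each base Gram?
#' @param validate Check symmetry and positive semidefiniteness of each Gram?
#' @return An object of class `"gram_stack"` with elements `grams` (list of
#'   `n x n` matrices), `specs`, `n`, `M`, `normalize`.
#' @export
gram_stack <- function(X, specs = default_kernel_bank(X), normalize = TRUE,
                       validate = TRUE) {
  X <- check_features(X)
  if (!length(specs)) stop("empty kernel bank", call. = FALSE)
  grams <- lapply(specs, function(sp) {
    K <- compute_gram(sp, X)
    if (normalize) K <- normalize_gram(K) else K
  })
  st <- new_gram_stack(grams, specs, normalize = normalize)
  if (validate) validate_gram_stack(st)
  st
}

new_gram_stack <- function(grams, specs, normalize = TRUE) {
  structure(list(grams = grams, specs = specs, n = nrow(grams[[1L]]),
                 M = length(grams), normalize = normalize),
            class = "gram_stack")
}

validate_gram_stack <- function(stack) {
  ns <- vapply(stack$grams, nrow, integer(1))
  if (length(unique(ns)) != 1L) {
    stop("all Gram matrices must share one dimension", call. = FALSE)
  }
  for (K in stack$grams) {
    if (max(abs(K - t(K))) > 1e-10) {
      stop("Gram matrix is not symmetric", call. = FALSE)
    }
    ev <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8 * max(sum(diag(K)) / nrow(K), 1)) {
      stop("Gram matrix is not positive semidefinite", call. = FALSE)
    }
  }
  invisible(stack)
}

#' @export
print.gram_stack <- function(x, ...) {
  cat(sprintf("<gram_stack> %d kernels on %d samples (%snormalized)\n",
              x$M, x$n, if (x$normalize) "" else "not "))
  invisible(x)
}

#' Simplex weights for the kernel combination
#'
#' Validates a vector of combination weights: non-negative, summing to one.
#'
#' @param mu Numeric vector of length `M`.
#' @return Object of class `"kernel_weights"` (a numeric vector).
#' @export
kernel_weights <- function(mu) {
  if (!is.numeric(mu) || !length(mu)) stop("'mu' must be numeric", call. = FALSE)
  if (any(mu < -1e-10)) stop("kernel weights must be non-negative", call. = FALSE)
  if (abs(sum(mu) - 1) > 1e-10) {
    stop("kernel weights must sum to one", call. = FALSE)
  }
  mu <- pmax(as.numeric(mu), 0)
  structure(mu, class = "kernel_weights")
}

#' Convex combination of base Gram matrices
#'
#' Returns \eqn{\sum_i \mu_i K_i}.  Any convex combination of PSD Gram
#' matrices remains PSD, so the combined kernel is again a Mercer kernel.
#'
#' @param stack A [gram_stack()].
#' @param weights A [kernel_weights()] vector of length `stack$M`.
#' @return An `n x n` matrix.
#' @export
combine_gram <- function(stack, weights) {
  stopifnot(inherits(stack, "gram_stack"))
  weights <- kernel_weights(unclass(weights))
  if (length(weights) != stack$M) {
    stop("weight vector length does not match the kernel stack", call. = FALSE)
  }
  K <- matrix(0, stack$n, stack$n)
  for (i in seq_len(stack$M)) {
    if (weights[i] != 0) K <- K + weights[i] * stack$grams[[i]]
  }
  K
}

# Combined cross-kernel block between training rows and new rows,
# consistent with the normalization used at training time.
cross_combined <- function(specs, weights, X_train, X_new, normalize) {
  X_train <- check_features(X_train)
  X_new <- check_features(X_new, "X_new")
  if (ncol(X_train) != ncol(X_new)) {
    stop("feature dimension of new samples does not match training data",
         call. = FALSE)
  }
  Kc <- matrix(0, nrow(X_train), nrow(X_new))
  for (i in seq_along(specs)) {
    w <- weights[i]
    if (w == 0) next
    G <- compute_gram(specs[[i]], X_train, X_new)
    if (normalize) {
      G <- normalize_cross(G, gram_diag(specs[[i]], X_train),
                           gram_diag(specs[[i]], X_new))
    }
    Kc <- Kc + w * G
  }
  Kc
}
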