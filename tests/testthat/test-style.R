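# Random small instance on a raw linear kernel, where the implicit style
# maps can be materialized and compared entry by entry.
random_style_instance <- function(seed, n = 12L, d = 3L, N = 3L) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d)
  group <- sort(sample.int(N, n, replace = TRUE))
  group <- as.integer(factor(group))  # no empty groups
  y <- random_labels(n, seed + 1L)
  alpha <- rnorm(n, sd = 0.4)
  list(X = X, y = y, group = group, alpha = alpha,
       K = tcrossprod(X),
       dataset = style_dataset(X, y, group))
}

style_from_alpha <- function(inst, lam, gamma) {
  dual <- structure(list(alpha = inst$alpha, bias = 0, lam = lam),
                    class = "lssvm_dual")
  update_style(inst$dataset, dual, kernel_weights(1), gamma)
}

test_that("the initial style model is the identity transformation", {
  inst <- random_style_instance(1)
  m <- init_style(inst$dataset, lam = 2, gamma = 0.25)
  expect_equal(m$scale, 1)
  expect_identical(transformed_gram(m, inst$K), inst$K)
  expect_equal(style_penalty(m, inst$K), 0)
  expect_error(init_style(inst$dataset, lam = 0, gamma = 1), "positive")
  m2 <- init_style(inst$dataset, lam = 1, gamma = 1)
  expect_equal(m2$scale, 0.5)
})

test_that("a zero dual snapshot is equivalent to initialization", {
  inst <- random_style_instance(2)
  dual0 <- structure(list(alpha = rep(0, 12), bias = 0, lam = 1),
                     class = "lssvm_dual")
  m <- update_style(inst$dataset, dual0, kernel_weights(1), gamma = 3)
  expect_identical(transformed_gram(m, inst$K), inst$K)
})

test_that("transformed_gram equals the explicit-feature computation", {
  for (seed in 1:10) {
    inst <- random_style_instance(seed, n = sample(6:14, 1L),
                                  d = sample(2:5, 1L))
    lam <- runif(1, 0.5, 2); gamma <- runif(1, 0.5, 4)
    m <- style_from_alpha(inst, lam, gamma)
    got <- transformed_gram(m, inst$K)
    want <- explicit_style_oracle(inst$X, inst$alpha, inst$group, lam,
                                  gamma)$gram
    expect_lt(max(abs(got - want)), 1e-6)
    expect_lt(max(abs(got - t(got))), 1e-10)
  }
})

test_that("style_penalty matches the explicit Frobenius norms", {
  for (seed in 1:6) {
    inst <- random_style_instance(seed + 20L)
    lam <- 1.3; gamma <- 0.8
    m <- style_from_alpha(inst, lam, gamma)
    pen <- style_penalty(m, inst$K)
    expect_gte(pen, 0)
    A <- materialize_A_linear(m, inst$dataset)
    want <- sum(vapply(A, function(a) norm(a - diag(ncol(inst$X)), "F")^2,
                       numeric(1)))
    expect_equal(pen, want, tolerance = 1e-8)
  }
})

test_that("the deviation from identity is linear in 1/gamma", {
  inst <- random_style_instance(31)
  m1 <- style_from_alpha(inst, lam = 1, gamma = 1)
  m2 <- style_from_alpha(inst, lam = 1, gamma = 2)
  A1 <- materialize_A_linear(m1, inst$dataset)
  A2 <- materialize_A_linear(m2, inst$dataset)
  I4 <- diag(ncol(inst$X))
  for (g in names(A1)) {
    expect_equal(norm(A1[[g]] - I4, "F"), 2 * norm(A2[[g]] - I4, "F"),
                 tolerance = 1e-10)
  }
  # and non-increasing across a wide gamma grid
  grid <- 10^seq(-2, 3, by = 1)
  norms <- vapply(grid, function(g) {
    A <- materialize_A_linear(style_from_alpha(inst, 1, g), inst$dataset)
    max(vapply(A, function(a) norm(a - I4, "F"), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("gamma -> Inf collapses the transformation", {
  inst <- random_style_instance(41)
  m <- style_from_alpha(inst, lam = 1, gamma = 1e8)
  expect_lt(max(abs(transformed_gram(m, inst$K) - inst$K)), 1e-6)
  m6 <- style_from_alpha(inst, lam = 1, gamma = 1e6)
  A <- materialize_A_linear(m6, inst$dataset)
  for (a in A) expect_lt(norm(a - diag(nrow(a)), "F"), 1e-3)
})

test_that("the hand-evaluated single-sample materialization is exact", {
  ds <- style_dataset(matrix(c(1, 0), 1, 2), 1, 1L)
  dual <- structure(list(alpha = 2, bias = 0, lam = 1), class = "lssvm_dual")
  m <- update_style(ds, dual, kernel_weights(1), gamma = 1)
  A <- materialize_A_linear(m, ds, w_bar = c(1, 0))
  expect_equal(A[["1"]], matrix(c(2, 0, 0, 1), 2, 2))
  expect_error(materialize_A_linear(m, ds,
                                    specs = list(kernel_spec("gaussian"))),
               "linear")
})

test_that("the snapshot update validates its inputs", {
  inst <- random_style_instance(51)
  bad <- structure(list(alpha = rep(0, 5), bias = 0, lam = 1),
                   class = "lssvm_dual")
  expect_error(update_style(inst$dataset, bad, kernel_weights(1), 1),
               "inconsistent")
  good <- structure(list(alpha = inst$alpha, bias = 0, lam = 1),
                    class = "lssvm_dual")
  expect_error(update_style(inst$dataset, good, kernel_weights(1), -1),
               "positive")
  m <- style_from_alpha(inst, 1, 1)
  expect_error(transformed_gram(m, inst$K[1:5, 1:5]), "every row")
})

test_that("appended rows inherit their declared group's transformation", {
  inst <- random_style_instance(61, n = 10L, d = 3L, N = 2L)
  lam <- 1; gamma <- 2
  m <- style_from_alpha(inst, lam, gamma)
  set.seed(99)
  Xnew <- matrix(rnorm(6), 2, 3)
  X_all <- rbind(inst$X, Xnew)
  K_ext <- tcrossprod(X_all)
  g_ext <- c(inst$group, 1L, 1L)
  got <- transformed_gram(m, K_ext, g_ext)
  want <- explicit_style_oracle(X_all, c(inst$alpha, 0, 0), g_ext, lam,
                                gamma)$gram
  expect_lt(max(abs(got - want)), 1e-6)
})
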