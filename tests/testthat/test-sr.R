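test_that("one outer iteration reproduces the plain multi-kernel fit", {
  d <- separable_dataset(seed = 2)
  bank <- default_kernel_bank(d$X)
  sr <- fit_sr(d, specs = bank, lam = 1, gamma = 5, max_outer = 1L)
  mk <- fit_mkl(gram_stack(d$X, bank), d$y, lam = 1)
  expect_lt(max(abs(unclass(sr$mkl$weights) - unclass(mk$weights))), 1e-10)
  expect_lt(max(abs(sr$mkl$dual$alpha - mk$dual$alpha)), 1e-10)
  expect_lt(abs(sr$mkl$dual$bias - mk$dual$bias), 1e-10)
})

test_that("the returned iterate attains the best monitored objective", {
  d <- generate_styled_data(synth_config(n_groups = 3, per_group = 20,
                                         style_strength = 1.5, seed = 9))
  sr <- fit_sr(d, max_outer = 10L)
  expect_true(all(is.finite(sr$objective_trace)))
  expect_equal(sr$objective, min(sr$objective_trace))
  expect_lte(sr$n_iter, 10L)
})

test_that("rule 2 under an identity style equals rule 1 exactly", {
  d <- separable_dataset(seed = 3)
  sr <- fit_sr(d, lam = 1, gamma = 5, max_outer = 1L)  # style frozen at I
  expect_true(all(sr$style$alpha_snapshot == 0))
  set.seed(4)
  Xn <- matrix(rnorm(8 * ncol(d$X)), 8)
  expect_identical(predict_rule2(sr, Xn, d$group[1L]),
                   predict_rule1(sr, Xn))
})

test_that("a huge gamma reproduces the style-free fit's predictions", {
  d <- generate_styled_data(synth_config(n_groups = 3, per_group = 24,
                                         style_strength = 1, seed = 17))
  bank <- default_kernel_bank(d$X)
  sr <- fit_sr(d, specs = bank, lam = 1, gamma = 1e8, max_outer = 5L)
  mk <- fit_mkl(gram_stack(d$X, bank), d$y, lam = 1)
  set.seed(18)
  Xn <- matrix(rnorm(20 * ncol(d$X)), 20)
  expect_identical(predict_rule1(sr, Xn), predict_mkl(mk, Xn, d$X))
  for (g in unique(d$group)) {
    expect_identical(predict_rule2(sr, Xn, g), predict_mkl(mk, Xn, d$X))
  }
})

test_that("rule 2 on a known style matches the explicit-matrix computation", {
  inst_seed <- 23
  d <- generate_styled_data(synth_config(n_groups = 2, per_group = 10,
                                         dim = 3, style_strength = 0.5,
                                         seed = inst_seed))
  bank <- list(kernel_spec("linear"))
  sr <- fit_sr(d, specs = bank, lam = 1, gamma = 8, max_outer = 3L,
               normalize = FALSE)
  set.seed(inst_seed + 1L)
  Xn <- matrix(rnorm(4 * 3), 4, 3)
  for (g in 1:2) {
    or <- explicit_style_oracle(rbind(d$X, Xn),
                                c(sr$style$alpha_snapshot, rep(0, 4)),
                                c(d$group, rep(g, 4)),
                                sr$style$lam, sr$style$gamma)
    dec <- or$gram[nrow(d$X) + 1:4, seq_len(nrow(d$X))] %*%
      sr$mkl$dual$alpha + sr$mkl$dual$bias
    expect_identical(predict_rule2(sr, Xn, g),
                     ifelse(dec >= 0, 1, -1)[, 1L])
  }
})

test_that("rule 3 reduces to rule 1 on separable data when styles are frozen", {
  d <- separable_dataset(seed = 6)
  sp <- make_splits(d, 0.5, held_out = 3L, seed = 7)
  sr <- fit_sr(sp$train, lam = 1, gamma = 5, max_outer = 5L)
  ho <- sp$test$group == 3L
  X0 <- sp$test$X[ho, , drop = FALSE]
  r1 <- predict_rule1(sr, X0)
  r3 <- predict_rule3(sr, X0, retrain = list(gamma = 1e10, max_outer = 1L))
  expect_identical(r3, r1)
})

test_that("rule 2 rejects unknown groups with a pointer to rule 3", {
  d <- separable_dataset(seed = 8)
  sr <- fit_sr(d, max_outer = 1L)
  expect_error(predict_rule2(sr, d$X[1:2, ], 99L), "predict_rule3")
})

test_that("evaluate_model is a recount of signed agreement", {
  d <- separable_dataset(seed = 10)
  sr <- fit_sr(d, max_outer = 2L)
  acc <- evaluate_model(sr, d, rule = 1)
  pred <- predict_rule1(sr, d$X)
  cm <- table(factor(pred, c(-1, 1)), factor(d$y, c(-1, 1)))
  expect_equal(acc, sum(diag(cm)) / sum(cm))
  flipped <- style_dataset(d$X, -d$y, d$group)
  expect_equal(evaluate_model(sr, flipped, rule = 1), 1 - acc)
  expect_error(evaluate_model(sr, d, rule = 5), "must be 1, 2 or 3")
})

test_that("training is deterministic: equal configs give identical models", {
  d <- generate_styled_data(synth_config(n_groups = 3, per_group = 18,
                                         style_strength = 1, seed = 12))
  a <- fit_sr(d, lam = 0.7, gamma = 12, max_outer = 6L)
  b <- fit_sr(d, lam = 0.7, gamma = 12, max_outer = 6L)
  expect_identical(unclass(a$mkl$weights), unclass(b$mkl$weights))
  expect_identical(a$mkl$dual$alpha, b$mkl$dual$alpha)
  expect_identical(a$mkl$dual$bias, b$mkl$dual$bias)
  set.seed(13)
  Xn <- matrix(rnorm(10 * ncol(d$X)), 10)
  expect_identical(predict_rule2(a, Xn, 2L), predict_rule2(b, Xn, 2L))
})
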