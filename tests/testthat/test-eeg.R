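# Small synthetic stand-in for the five-set single-channel EEG layout:
# one directory per set, one integer amplitude per line per file.
write_fake_bonn <- function(root, sets = c("A", "B", "C", "D", "E"),
                            files_per_set = 4L, len = 32L, seed = 1L) {
  set.seed(seed)
  for (s in sets) {
    dir.create(file.path(root, s), recursive = TRUE, showWarnings = FALSE)
    amp <- switch(s, A = 40, B = 60, C = 120, D = 150, E = 400)
    for (i in seq_len(files_per_set)) {
      v <- as.integer(round(amp * sin(seq_len(len) / 3 + i) +
                              rnorm(len, sd = amp / 4)))
      writeLines(as.character(v), file.path(root, s, sprintf("%s%03d.txt",
                                                             s, i)))
    }
  }
  root
}

test_that("the loader reads every set and tolerates a trailing blank line", {
  root <- write_fake_bonn(file.path(tempdir(), "bonn1"))
  recs <- load_bonn(root)
  expect_length(recs, 20L)
  expect_setequal(unique(vapply(recs, `[[`, "", "set_id")),
                  c("A", "B", "C", "D", "E"))
  f <- file.path(root, "A", "A001.txt")
  cat("\n", file = f, append = TRUE)
  recs2 <- load_bonn(root)
  expect_equal(length(recs2[[1L]]$values), 32L)
})

test_that("the loader reports missing sets and malformed lines precisely", {
  root <- write_fake_bonn(file.path(tempdir(), "bonn2"), sets = c("A", "B"))
  expect_error(load_bonn(root), "C, D, E")
  expect_silent(load_bonn(root, sets = c("A", "B")))
  empty <- file.path(tempdir(), "bonn-empty")
  dir.create(empty, showWarnings = FALSE)
  expect_error(load_bonn(empty), "expected one subdirectory")
  bad <- file.path(root, "A", "A001.txt")
  lines <- readLines(bad)
  lines[3L] <- "not-a-number"
  writeLines(lines, bad)
  expect_error(load_bonn(root, sets = c("A", "B")), "line 3")
})

test_that("original Bonn file prefixes map onto sets A-E", {
  root <- file.path(tempdir(), "bonn3")
  for (p in c("Z", "O", "N", "F", "S")) {
    dir.create(file.path(root, p), recursive = TRUE, showWarnings = FALSE)
    writeLines(c("1", "2", "3"), file.path(root, p, paste0(p, "001.txt")))
  }
  recs <- load_bonn(root)
  expect_setequal(vapply(recs, `[[`, "", "set_id"),
                  c("A", "B", "C", "D", "E"))
})

test_that("kernel PCA turns recordings into a labeled style dataset", {
  root <- write_fake_bonn(file.path(tempdir(), "bonn4"), files_per_set = 5L)
  recs <- load_bonn(root)
  ds <- kpca_features(recs, n_components = 3L)
  expect_s3_class(ds, "style_dataset")
  expect_equal(dim(ds$X), c(25L, 3L))
  expect_setequal(unique(ds$group), 1:5)
  expect_true(all(ds$y[ds$group %in% 1:2] == 1))
  expect_true(all(ds$y[ds$group %in% 3:5] == -1))
  # centered kernel: projected features have zero mean in feature space
  expect_lt(max(abs(colMeans(ds$X))), 1e-8)
  expect_error(kpca_features(recs, n_components = 100L), "between 1")
})

test_that("experiment splits follow the two split designs", {
  root <- write_fake_bonn(file.path(tempdir(), "bonn5"), files_per_set = 6L)
  ds <- kpca_features(load_bonn(root), n_components = 4L)
  s1 <- build_paper_splits(ds, "DS.1", seed = 1)
  expect_setequal(unique(s1$train$group), c(1L, 2L, 5L))
  expect_setequal(unique(s1$test$group), c(1L, 2L, 5L))
  s3 <- build_paper_splits(ds, "DS.3", seed = 1)
  expect_false(3L %in% s3$train$group)
  expect_true(3L %in% s3$test$group)
  s4 <- build_paper_splits(ds, "DS.4", seed = 1)
  expect_false(1L %in% s4$train$group)
  s4b <- build_paper_splits(ds, "DS.4", seed = 1, held_out = 5L)
  expect_false(5L %in% s4b$train$group)
  a <- build_paper_splits(ds, "DS.2", seed = 1)
  b <- build_paper_splits(ds, "DS.2", seed = 2)
  expect_false(identical(sort(apply(a$train$X, 1, paste, collapse = ",")),
                         sort(apply(b$train$X, 1, paste, collapse = ","))))
})
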