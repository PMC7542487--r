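#' Configuration of the synthetic stylized-data generator
#'
#' Describes a style-grouped binary classification problem: two
#' class-conditional isotropic gaussian clusters separated by `class_sep`
#' along the first axis, with every style group observed through its own
#' random affine distortion (a rotation `expm(style_strength * B)` for a
#' random unit-norm skew-symmetric `B`, plus a bounded random shift of
#' magnitude `0.5 * style_strength`).  `style_strength = 0` makes every
#' group's distortion exactly the identity.
#'
#' @param n_groups Number of style groups `N`.
#' @param per_group Samples per group `t`.
#' @param dim Feature dimension `d`.
#' @param class_sep Distance between the class means (units of feature
#'   space; with `noise_sd = 1` a separation of 3 leaves moderate class
#'   overlap).
#' @param style_strength Non-negative magnitude `s` of the per-group
#'   distortion.
#' @param noise_sd Isotropic within-class standard deviation.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return Object of class `"synth_config"`.
#' @export
synth_config <- function(n_groups = 4L, per_group = 30L, dim = 6L,
                         class_sep = 3, style_strength = 1, noise_sd = 1,
                         seed = 1L) {
  cfg <- list(n_groups = as.integer(n_groups), per_group = as.integer(per_group),
              dim = as.integer(dim), class_sep = as.numeric(class_sep),
              style_strength = as.numeric(style_strength),
              noise_sd = as.numeric(noise_sd), seed = as.integer(seed))
  if (cfg$n_groups < 1L || cfg$per_group < 1L || cfg$dim < 1L) {
    stop("counts must be positive", call. = FALSE)
  }
  if (is.na(cfg$style_strength) || cfg$style_strength < 0) {
    stop("'style_strength' must be non-negative", call. = FALSE)
  }
  if (is.na(cfg$noise_sd) || cfg$noise_sd <= 0) {
    stop("'noise_sd' must be positive", call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Generate a synthetic style-grouped dataset
#'
#' Draws balanced binary samples for every style group and pushes them
#' through the group's affine distortion (see [synth_config()]).
#'
#' @param config A [synth_config()].
#' @return A [style_dataset()].
#' @examples
#' d <- generate_styled_data(synth_config(n_groups = 3, per_group = 10))
#' d$group_sizes
#' @export
generate_styled_data <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    d <- config$dim
    rows <- list()
    ys <- list()
    gs <- list()
    for (j in seq_len(config$n_groups)) {
      if (config$style_strength > 0) {
        B <- matrix(stats::rnorm(d * d), d, d)
        B <- B - t(B)
        B <- B / max(norm(B, "F"), .Machine$double.eps)
        R <- pracma::expm(config$style_strength * B)
        shift <- stats::rnorm(d)
        shift <- 0.5 * config$style_strength * shift / max(sqrt(sum(shift^2)),
                                                           .Machine$double.eps)
      } else {
        R <- diag(d)
        shift <- rep(0, d)
      }
      n_pos <- ceiling(config$per_group / 2)
      y_j <- c(rep(1, n_pos), rep(-1, config$per_group - n_pos))
      mu <- outer(y_j, c(config$class_sep / 2, rep(0, d - 1L)))
      Z <- mu + matrix(stats::rnorm(config$per_group * d, sd = config$noise_sd),
                       config$per_group, d)
      rows[[j]] <- Z %*% t(R) + matrix(shift, config$per_group, d, byrow = TRUE)
      ys[[j]] <- y_j
      gs[[j]] <- rep(j, config$per_group)
    }
    style_dataset(do.call(rbind, rows), unlist(ys), unlist(gs))
  })
}

#' Split a style-grouped dataset into train and test parts
#'
#' Two split designs are supported.  With `held_out` empty, every group is
#' split `train_fraction` / rest, stratified by label within the group, so
#' all test styles also occur in training.  Groups named in `held_out`
#' appear only in the test set, giving the test set a style absent from
#' training.
#'
#' @param dataset A [style_dataset()].
#' @param train_fraction Per-group training fraction in (0, 1).
#' @param held_out Integer vector of group ids excluded from training.
#' @param seed Integer seed controlling the random memberships.
#' @return List with elements `train` and `test`, both [style_dataset()]s.
#' @export
make_splits <- function(dataset, train_fraction = 0.5, held_out = integer(0),
                        seed = 1L) {
  stopifnot(inherits(dataset, "style_dataset"))
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1) {
    stop("'train_fraction' must lie in (0, 1)", call. = FALSE)
  }
  held_out <- as.integer(held_out)
  ids <- sort(unique(dataset$group))
  if (!all(held_out %in% ids)) {
    stop("'held_out' names a group absent from the dataset", call. = FALSE)
  }
  if (all(ids %in% held_out)) {
    stop("at least one group must remain in the training set", call. = FALSE)
  }
  with_seed(seed, {
    tr_idx <- integer(0)
    for (g in setdiff(ids, held_out)) {
      gi <- which(dataset$group == g)
      if (length(gi) < 2L) {
        stop("cannot split a group with fewer than 2 samples", call. = FALSE)
      }
      for (lab in unique(dataset$y[gi])) {
        cell <- gi[dataset$y[gi] == lab]
        k <- round(train_fraction * length(cell))
        k <- min(max(k, if (length(cell) > 1L) 1L else 0L), length(cell))
        if (length(cell) > 1L) k <- min(k, length(cell) - 1L)
        tr_idx <- c(tr_idx, sample(cell, k))
      }
    }
    tr_idx <- sort(tr_idx)
    te_idx <- setdiff(seq_along(dataset$y), tr_idx)
    list(train = style_dataset(dataset$X[tr_idx, , drop = FALSE],
                               dataset$y[tr_idx], dataset$group[tr_idx]),
         test = style_dataset(dataset$X[te_idx, , drop = FALSE],
                              dataset$y[te_idx], dataset$group[te_idx]))
  })
}
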