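#' Load Bonn-style EEG recordings from ASCII files
#'
#' Reads the standard single-channel EEG layout: one subdirectory per
#' recording set, each file holding one integer amplitude per line.  Set
#' directories may be named `A`--`E` or by the original file prefixes
#' `Z, O, N, F, S` (which map to `A, B, C, D, E`).  A trailing blank line is
#' tolerated.
#'
#' @param dir_path Root directory of the download.
#' @param sets Recording sets that must be present; an absent set raises an
#'   error naming it.
#' @return List of recordings, each a list with `set_id`, `values` (integer
#'   vector), `source_file`.
#' @export
load_bonn <- function(dir_path, sets = c("A", "B", "C", "D", "E")) {
  if (!dir.exists(dir_path)) {
    stop("directory not found: ", dir_path, call. = FALSE)
  }
  alias <- c(Z = "A", O = "B", N = "C", F = "D", S = "E")
  subdirs <- list.dirs(dir_path, recursive = FALSE, full.names = TRUE)
  if (!length(subdirs)) {
    stop("empty directory: expected one subdirectory per recording set ",
         "(A-E or Z/O/N/F/S), each containing one-integer-per-line ASCII ",
         "files", call. = FALSE)
  }
  set_of <- function(nm) {
    nm <- toupper(nm)
    if (nm %in% names(alias)) unname(alias[nm])
    else if (nm %in% c("A", "B", "C", "D", "E")) nm
    else NA_character_
  }
  found <- stats::setNames(vapply(basename(subdirs), set_of, character(1)),
                           subdirs)
  missing <- setdiff(sets, found[!is.na(found)])
  if (length(missing)) {
    stop("recording set(s) absent from ", dir_path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  recs <- list()
  for (sd in names(found)) {
    sid <- found[[sd]]
    if (is.na(sid) || !(sid %in% sets)) next
    for (f in sort(list.files(sd, full.names = TRUE))) {
      lines <- readLines(f, warn = FALSE)
      while (length(lines) && !nzchar(trimws(lines[length(lines)]))) {
        lines <- lines[-length(lines)]
      }
      vals <- suppressWarnings(as.integer(trimws(lines)))
      if (anyNA(vals)) {
        bad <- which(is.na(vals))[1L]
        stop(sprintf("malformed amplitude in %s at line %d", f, bad),
             call. = FALSE)
      }
      if (!length(vals)) {
        stop("empty recording file: ", f, call. = FALSE)
      }
      recs[[length(recs) + 1L]] <- list(set_id = sid, values = vals,
                                        source_file = basename(f))
    }
  }
  recs
}

#' Kernel-PCA feature extraction for EEG recordings
#'
#' Turns each raw recording into one feature row by kernel principal
#' component analysis on the amplitude vectors (recordings are truncated to
#' the shortest common length).  The result is a [style_dataset()]: group id
#' is the recording set (A=1 ... E=5), label +1 for the healthy sets (A, B)
#' and -1 for the patient sets (C, D, E).
#'
#' @param recordings Output of [load_bonn()].
#' @param n_components Number of kernel principal components per recording.
#' @param width Gaussian kernel bandwidth; defaults to the median pairwise
#'   distance between the amplitude vectors.
#' @return A [style_dataset()] with `n_components` feature columns.
#' @export
kpca_features <- function(recordings, n_components = 70L, width = NULL) {
  if (!length(recordings)) stop("no recordings", call. = FALSE)
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > length(recordings)) {
    stop("'n_components' must be between 1 and the number of recordings",
         call. = FALSE)
  }
  len <- min(vapply(recordings, function(r) length(r$values), integer(1)))
  Xraw <- t(vapply(recordings, function(r) as.numeric(r$values[seq_len(len)]),
                   numeric(len)))
  if (is.null(width)) width <- median_heuristic(Xraw)
  kp <- kernlab::kpca(Xraw, kernel = "rbfdot",
                      kpar = list(sigma = 1 / (2 * width^2)),
                      features = n_components)
  feats <- kernlab::rotated(kp)[, seq_len(n_components), drop = FALSE]
  set_ids <- vapply(recordings, function(r) r$set_id, character(1))
  group <- match(set_ids, c("A", "B", "C", "D", "E"))
  label <- ifelse(set_ids %in% c("A", "B"), 1, -1)
  style_dataset(feats, label, group)
}

#' Train/test splits mirroring the EEG experiment designs
#'
#' Builds the four experiment layouts over the recording sets: `DS.1`
#' (50/50 within sets A, B, E), `DS.2` (50/50 within B, D, E), and `DS.3` /
#' `DS.4` (sets A, C, E with one set entirely held out of training, so the
#' test set carries a style never seen in training).  Which set is held out
#' in the second pair is configurable via `held_out`; the defaults hold out
#' C for `DS.3` and A for `DS.4`.
#'
#' @param dataset A [style_dataset()] whose group ids are 1--5 for sets A--E
#'   (as produced by [kpca_features()]).
#' @param ds_id One of `"DS.1"`, `"DS.2"`, `"DS.3"`, `"DS.4"`.
#' @param seed Integer seed for the random memberships.
#' @param held_out Optional group id (1--5) overriding the default held-out
#'   set for `DS.3` / `DS.4`.
#' @return List with `train` and `test` [style_dataset()]s.
#' @export
build_paper_splits <- function(dataset, ds_id = c("DS.1", "DS.2", "DS.3",
                                                  "DS.4"),
                               seed = 1L, held_out = NULL) {
  stopifnot(inherits(dataset, "style_dataset"))
  ds_id <- match.arg(ds_id)
  sets <- switch(ds_id,
                 DS.1 = c(1L, 2L, 5L),   # A, B, E
                 DS.2 = c(2L, 4L, 5L),   # B, D, E
                 c(1L, 3L, 5L))          # A, C, E
  keep <- dataset$group %in% sets
  if (!any(keep)) stop("dataset holds none of the sets of ", ds_id,
                       call. = FALSE)
  sub <- style_dataset(dataset$X[keep, , drop = FALSE], dataset$y[keep],
                       dataset$group[keep])
  ho <- if (ds_id %in% c("DS.3", "DS.4")) {
    h <- if (is.null(held_out)) switch(ds_id, DS.3 = 3L, DS.4 = 1L)
         else as.integer(held_out)
    if (!(h %in% sets)) stop("'held_out' must be one of the sets of ", ds_id,
                             call. = FALSE)
    h
  } else integer(0)
  make_splits(sub, train_fraction = 0.5, held_out = ho, seed = seed)
}
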