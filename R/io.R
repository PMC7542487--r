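#' Write a style-grouped dataset to delimited text
#'
#' Column layout: header `group,label,f1..fd`; labels are written as
#' `+1` / `-1` and group ids as positive integers.
#'
#' @param dataset A [style_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "style_dataset"))
  d <- ncol(dataset$X)
  header <- paste(c("group", "label", paste0("f", seq_len(d))), collapse = ",")
  body <- vapply(seq_len(nrow(dataset$X)), function(r) {
    paste(c(dataset$group[r],
            sprintf("%+d", as.integer(dataset$y[r])),
            sprintf("%.17g", dataset$X[r, ])), collapse = ",")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a style-grouped dataset from delimited text
#'
#' Inverse of [write_dataset()]: expects the header `group,label,f1..fd`.
#'
#' @param path Input file path.
#' @return A [style_dataset()].
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("group", "label")
  if (!all(need %in% names(df)) || ncol(df) < 3L) {
    stop("expected columns 'group', 'label', 'f1'..'fd' in ", path,
         call. = FALSE)
  }
  fcols <- setdiff(names(df), need)
  style_dataset(as.matrix(df[fcols]), df$label, df$group)
}

model_format_version <- 1L

#' Serialize a trained model to a two-file artifact
#'
#' Writes `<prefix>.hdr` (structured text: dimensions, hyperparameters,
#' kernel specs, weights, bias, group table, objective traces) and
#' `<prefix>.bin` (little-endian doubles: dual coefficients, style
#' snapshot, labels, training features).  Reloading with [load_sr_model()]
#' reproduces predictions bit-exactly.
#'
#' @param model An `"sr_model"`.
#' @param prefix Path prefix of the artifact (no extension).
#' @return `prefix`, invisibly.
#' @export
save_sr_model <- function(model, prefix) {
  stopifnot(inherits(model, "sr_model"))
  n <- nrow(model$train$X)
  d <- ncol(model$train$X)
  fmt <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  spec_line <- function(sp) {
    switch(sp$family,
      linear = "kernel linear",
      polynomial = sprintf("kernel polynomial degree=%d coef0=%.17g",
                           sp$degree, sp$coef0),
      gaussian = sprintf("kernel gaussian width=%.17g", sp$width))
  }
  hdr <- c(
    sprintf("format: %d", model_format_version),
    sprintf("n: %d", n),
    sprintf("d: %d", d),
    sprintf("M: %d", length(model$specs)),
    sprintf("lam: %.17g", model$lam),
    sprintf("gamma: %.17g", model$gamma),
    sprintf("style_lam: %.17g", model$style$lam),
    sprintf("style_gamma: %.17g", model$style$gamma),
    sprintf("normalize: %d", as.integer(model$normalize)),
    sprintf("converged: %d", as.integer(model$converged)),
    sprintf("n_iter: %d", model$n_iter),
    paste("mu:", fmt(unclass(model$mkl$weights))),
    paste("style_mu:", if (is.null(model$style$weights)) "none"
                       else fmt(unclass(model$style$weights))),
    sprintf("bias: %.17g", model$mkl$dual$bias),
    paste("group:", paste(model$train$group, collapse = " ")),
    paste("objective_trace:", fmt(model$objective_trace)),
    paste("mkl_trace:", fmt(model$mkl$objective_trace)),
    vapply(model$specs, spec_line, character(1)))
  writeLines(hdr, paste0(prefix, ".hdr"))
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  writeBin(c(model$mkl$dual$alpha, model$style$alpha_snapshot,
             model$train$y, as.numeric(model$train$X)),
           con, size = 8L, endian = "little")
  invisible(prefix)
}

#' Load a serialized model
#'
#' @param prefix Path prefix used in [save_sr_model()].
#' @return An `"sr_model"` whose predictions are bit-identical to the saved
#'   model's.
#' @export
load_sr_model <- function(prefix) {
  hpath <- paste0(prefix, ".hdr")
  bpath <- paste0(prefix, ".bin")
  if (!file.exists(hpath) || !file.exists(bpath)) {
    stop("model artifact not found at prefix ", prefix, call. = FALSE)
  }
  lines <- readLines(hpath)
  val <- function(key) {
    hit <- grep(paste0("^", key, ": "), lines, value = TRUE)
    if (!length(hit)) stop("missing header field: ", key, call. = FALSE)
    sub(paste0("^", key, ": "), "", hit[1L])
  }
  nums <- function(key) as.numeric(strsplit(val(key), " ", fixed = TRUE)[[1L]])
  n <- as.integer(val("n")); d <- as.integer(val("d"))
  M <- as.integer(val("M"))
  lam <- as.numeric(val("lam")); gamma <- as.numeric(val("gamma"))
  normalize <- as.integer(val("normalize")) == 1L
  specs <- lapply(grep("^kernel ", lines, value = TRUE), parse_kernel_line)
  if (length(specs) != M) stop("corrupt header: kernel count mismatch",
                               call. = FALSE)
  con <- file(bpath, "rb")
  on.exit(close(con))
  raw <- readBin(con, "double", n = 3L * n + n * d, size = 8L,
                 endian = "little")
  if (length(raw) != 3L * n + n * d) {
    stop("corrupt binary payload", call. = FALSE)
  }
  alpha <- raw[seq_len(n)]
  snap <- raw[n + seq_len(n)]
  y <- raw[2L * n + seq_len(n)]
  X <- matrix(raw[3L * n + seq_len(n * d)], n, d)
  group <- as.integer(strsplit(val("group"), " ", fixed = TRUE)[[1L]])
  train <- style_dataset(X, y, group)
  dual <- structure(list(alpha = alpha, bias = as.numeric(val("bias")),
                         lam = lam), class = "lssvm_dual")
  style_mu_raw <- val("style_mu")
  style_w <- if (identical(style_mu_raw, "none")) NULL
             else kernel_weights(as.numeric(strsplit(style_mu_raw, " ")[[1L]]))
  style <- new_style_model(snap, as.numeric(val("style_lam")),
                           as.numeric(val("style_gamma")), group,
                           weights = style_w)
  stack <- gram_stack(X, specs, normalize = normalize, validate = FALSE)
  mkl <- structure(list(weights = kernel_weights(nums("mu")), dual = dual,
                        stack = stack, lam = lam,
                        objective_trace = nums("mkl_trace"),
                        converged = TRUE,
                        n_iter = length(nums("mkl_trace"))),
                   class = "mkl_model")
  structure(list(mkl = mkl, style = style, train = train, specs = specs,
                 normalize = normalize, lam = lam, gamma = gamma,
                 objective_trace = nums("objective_trace"),
                 converged = as.integer(val("converged")) == 1L,
                 n_iter = as.integer(val("n_iter"))),
            class = "sr_model")
}

parse_kernel_line <- function(line) {
  parts <- strsplit(trimws(line), "[[:space:]]+")[[1L]]
  if (length(parts) < 2L || parts[1L] != "kernel") {
    stop("malformed kernel line: ", line, call. = FALSE)
  }
  family <- parts[2L]
  kv <- list()
  for (p in parts[-(1:2)]) {
    eq <- strsplit(p, "=", fixed = TRUE)[[1L]]
    if (length(eq) != 2L) stop("malformed kernel option: ", p, call. = FALSE)
    kv[[eq[1L]]] <- as.numeric(eq[2L])
  }
  bad <- setdiff(names(kv), c("degree", "width", "coef0"))
  if (length(bad)) stop("unknown kernel option(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  do.call(kernel_spec, c(list(family = family), kv))
}
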