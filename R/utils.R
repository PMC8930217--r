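# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' previous RNG state so callers' random streams are untouched.
#' @noRd
with_seed <- function(seed, expr) {
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
  force(expr)
}

#' Round half away from zero (half-up for positive arguments)
#'
#' Deterministic alternative to [round()]'s banker's rounding; used by the
#' seed-count formula so results do not depend on IEEE round-to-even.
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

#' Stratified k-fold assignment
#'
#' Returns an integer vector of fold ids in 1..k, balanced within each class.
#' Deterministic for a fixed seed.
#' @noRd
stratified_folds <- function(labels, k, seed) {
  labels <- as.factor(labels)
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Stratified train/test split
#'
#' @return list(train = integer indices, test = integer indices)
#' @noRd
stratified_split <- function(labels, train_frac, seed) {
  labels <- as.factor(labels)
  train <- integer(0)
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      n_tr <- max(1L, round(length(idx) * train_frac))
      train <- c(train, idx[sample.int(length(idx))][seq_len(n_tr)])
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Write a file atomically (temp file in the same directory, then rename)
#' @noRd
atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    stop("failed to move temporary file into place at ", path)
  }
  invisible(path)
}
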