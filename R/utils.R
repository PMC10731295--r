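# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the caller's RNG state,
#' so package functions never consume or perturb global random state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Reproducible stream of sub-seeds from one master seed. Values stay in
# [1, 2^31 - 2] so they are always valid set.seed() inputs.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stopf("non-finite values in %s", what)
  invisible(x)
}

# Stratified fold assignment: within each class, shuffled samples are dealt
# round-robin over folds, so fold class counts differ by at most one.
#' @noRd
stratified_folds <- function(labels, k, seed) {
  if (k < 2) stopf("cv_folds must be >= 2")
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  lapply(seq_len(k), function(f) which(fold == f))
}
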