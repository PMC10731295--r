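# Successive projections algorithm (SPA) band selection and cross-validated
# RMSE sizing of the selected subset.

#' SPA projection chain
#'
#' Starting from band `start`, repeatedly (i) projects every unselected
#' column onto the orthogonal complement of the most recently selected
#' (projected) column and (ii) selects the column of maximal Euclidean norm.
#' Ties break to the lowest band index. The chained projections make each
#' newly selected column orthogonal to all previously selected ones, which
#' is what minimizes collinearity in the downstream regression.
#'
#' @param X n x B spectra matrix (no all-zero columns).
#' @param start starting band index, `k(0)`.
#' @param n_select chain length N, `1 <= N <= min(n - 1, B)`.
#' @param tol norm below which the remaining columns count as collinearly
#'   exhausted (error reporting the achievable N).
#' @return integer vector `c(start, k1, ..., k_{N-1})`.
#' @export
spa_chain <- function(X, start, n_select, tol = 1e-12) {
  X <- as.matrix(X)
  n <- nrow(X); B <- ncol(X)
  if (start < 1 || start > B) stopf("start band out of range")
  if (n_select < 1 || n_select > min(n - 1, B))
    stopf("n_select must lie in [1, min(n - 1, B)] = [1, %d]", min(n - 1, B))
  if (any(colSums(X^2) == 0)) stopf("X has an all-zero column")
  sel <- integer(n_select)
  sel[1L] <- as.integer(start)
  if (n_select == 1L) return(sel)
  W <- X
  for (step in 2:n_select) {
    v <- W[, sel[step - 1L]]
    W <- W - v %*% (crossprod(v, W) / sum(v^2))
    norms2 <- colSums(W^2)
    norms2[sel[1:(step - 1L)]] <- -Inf
    if (sqrt(max(norms2)) < tol)
      stopf("columns collinearly exhausted after %d selections (requested %d)",
            step - 1L, n_select)
    sel[step] <- which.max(norms2)
  }
  sel
}

# Pooled k-fold RMSE of an intercept + selected-bands linear regression of
# the numeric label. Inf marks an infeasible (rank-deficient) candidate.
cv_rmse_linear <- function(Xsel, y, folds) {
  se <- 0; m <- 0L
  for (f in folds) {
    tr <- setdiff(seq_along(y), f)
    fit <- stats::lm.fit(cbind(1, Xsel[tr, , drop = FALSE]), y[tr])
    if (anyNA(fit$coefficients)) return(Inf)
    pred <- cbind(1, Xsel[f, , drop = FALSE]) %*% fit$coefficients
    se <- se + sum((y[f] - pred)^2)
    m <- m + length(f)
  }
  sqrt(se / m)
}

#' SPA band selection with RMSE-curve model sizing
#'
#' For every candidate subset size N in `[n_min, n_max]` and every candidate
#' start band, runs the SPA chain on the training spectra and scores the
#' first N chained bands by the k-fold cross-validated RMSE of a multiple
#' linear regression of the numeric class label on those bands. Records the
#' minimum-over-starts RMSE per N and picks the N (and its start) minimizing
#' RMSE; ties break to the smallest N, then the smallest start index, so
#' runs are bit-reproducible.
#'
#' @param train_spectra a [spectrum_set()] (training partition only).
#' @param n_min,n_max candidate subset sizes; `n_max` must be below the
#'   smallest CV training-fold size.
#' @param cv_folds number of folds (stratified by label).
#' @param seed seed for the fold assignment.
#' @param starts candidate start bands (default: every band).
#' @return a `band_selection`: `selected_indices` (chain order),
#'   `selected_wavelengths_nm`, `start_index`, `n_bands`, `rmse_curve`
#'   (data.frame N / best RMSE / best start), `chosen_rmse`.
#' @export
select_bands <- function(train_spectra, n_min = 1, n_max = 16, cv_folds = 5,
                         seed = 1, starts = NULL) {
  stopifnot(inherits(train_spectra, "spectrum_set"))
  X <- train_spectra$spectra
  y <- as.numeric(train_spectra$labels)
  n <- nrow(X); B <- ncol(X)
  if (n_min < 1 || n_min > n_max) stopf("need 1 <= n_min <= n_max")
  folds <- stratified_folds(train_spectra$labels, cv_folds, seed)
  min_train <- n - max(lengths(folds))
  if (n_max >= min_train)
    stopf("n_max (%d) must be below the smallest CV training-fold size (%d)",
          n_max, min_train)
  starts <- as.integer(starts %||% seq_len(B))
  if (any(starts < 1L | starts > B)) stopf("start indices out of range")

  ns <- n_min:n_max
  best_rmse <- rep(Inf, length(ns))
  best_start <- rep(NA_integer_, length(ns))
  for (s in starts) {
    chain <- tryCatch(spa_chain(X, s, n_max),
                      error = function(e) NULL)
    if (is.null(chain)) next
    for (j in seq_along(ns)) {
      r <- cv_rmse_linear(X[, chain[1:ns[j]], drop = FALSE], y, folds)
      if (r < best_rmse[j]) {  # strict: ties keep the lower start index
        best_rmse[j] <- r
        best_start[j] <- s
      }
    }
  }
  if (all(!is.finite(best_rmse))) stopf("no feasible SPA candidate found")
  jbest <- which.min(best_rmse)  # first minimum -> smallest N on ties
  n_chosen <- ns[jbest]
  start_chosen <- best_start[jbest]
  chain <- spa_chain(X, start_chosen, n_chosen)
  structure(
    list(selected_indices = chain,
         selected_wavelengths_nm = train_spectra$wavelengths_nm[chain],
         start_index = start_chosen,
         n_bands = n_chosen,
         rmse_curve = data.frame(n_bands = ns, rmse = best_rmse,
                                 start = best_start),
         chosen_rmse = best_rmse[jbest]),
    class = "band_selection")
}

#' @export
print.band_selection <- function(x, ...) {
  cat(sprintf("<band_selection> N = %d bands from start %d, CV RMSE = %.4f\n",
              x$n_bands, x$start_index, x$chosen_rmse))
  cat("  wavelengths (nm):", paste(sprintf("%.1f", x$selected_wavelengths_nm),
                                   collapse = ", "), "\n")
  invisible(x)
}

#' Restrict a spectrum set to selected bands
#'
#' Columns are subset in chain order (the SPA selection order), wavelengths
#' accordingly.
#'
#' @param ss a [spectrum_set()].
#' @param sel a `band_selection`, or an integer index vector.
#' @return [spectrum_set()] restricted to the selected bands.
#' @export
apply_selection <- function(ss, sel) {
  stopifnot(inherits(ss, "spectrum_set"))
  idx <- if (inherits(sel, "band_selection")) sel$selected_indices else as.integer(sel)
  if (any(idx < 1L | idx > ncol(ss$spectra))) stopf("selection index out of range")
  out <- ss
  out$spectra <- ss$spectra[, idx, drop = FALSE]
  out$wavelengths_nm <- ss$wavelengths_nm[idx]
  # chain order is informative, not sorted; bypass the strictly-increasing check
  structure(out, class = "spectrum_set")
}

#' Serialize / deserialize a band selection as JSON
#'
#' @param sel a `band_selection`.
#' @param path JSON path.
#' @export
write_band_selection <- function(sel, path) {
  stopifnot(inherits(sel, "band_selection"))
  jsonlite::write_json(unclass(sel), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_band_selection
#' @export
read_band_selection <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$selected_indices <- as.integer(x$selected_indices)
  x$rmse_curve <- as.data.frame(x$rmse_curve)
  structure(x, class = "band_selection")
}
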