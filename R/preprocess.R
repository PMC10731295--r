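# Spectral pretreatments: standard normal variate, multiplicative scatter
# correction, Savitzky-Golay smoothing.

#' Standard normal variate (SNV)
#'
#' Centers and scales each spectrum independently:
#' `(x - mean(x)) / sd(x)`, with the sample (n-1) standard deviation.
#'
#' @param x numeric vector, or matrix with one spectrum per row.
#' @param tol spectra with sd below `tol` are an error (degenerate spectrum).
#' @return object of the same shape with every spectrum at mean 0, sd 1.
#' @export
snv <- function(x, tol = 1e-12) {
  if (is.matrix(x)) {
    out <- x
    for (i in seq_len(nrow(x))) out[i, ] <- snv_one(x[i, ], tol, rownames(x)[i] %||% i)
    return(out)
  }
  snv_one(x, tol, "spectrum")
}

snv_one <- function(x, tol, id) {
  if (length(x) < 2) stopf("SNV needs at least 2 bands")
  s <- stats::sd(x)
  if (!is.finite(s) || s < tol)
    stopf("SNV: near-constant spectrum (sd = %g) for sample %s", s, id)
  (x - mean(x)) / s
}

#' Multiplicative scatter correction (MSC)
#'
#' Regresses each spectrum on a reference spectrum by ordinary least squares,
#' `x ~ a + b * ref`, and inverts the fit: `x' = (x - a) / b`. The reference
#' defaults to the column mean of `spectra` (fit it on the training partition
#' and pass it explicitly for held-out data).
#'
#' @param spectra matrix with one spectrum per row.
#' @param reference reference spectrum; `NULL` uses the dataset mean, which
#'   requires at least 2 spectra.
#' @param tol minimum |slope|; smaller slopes are an error for that sample.
#' @return corrected matrix with the reference attached as attribute
#'   `msc_reference`.
#' @export
msc <- function(spectra, reference = NULL, tol = 1e-8) {
  spectra <- as.matrix(spectra)
  if (is.null(reference)) {
    if (nrow(spectra) < 2) stopf("MSC with a dataset-mean reference needs >= 2 spectra")
    reference <- colMeans(spectra)
  }
  if (length(reference) != ncol(spectra)) stopf("reference length mismatch")
  rc <- reference - mean(reference)
  vr <- sum(rc^2)
  if (vr < tol) stopf("MSC reference is (near-)constant")
  out <- spectra
  for (i in seq_len(nrow(spectra))) {
    x <- spectra[i, ]
    b <- sum((x - mean(x)) * rc) / vr
    if (abs(b) < tol)
      stopf("MSC: slope %g below tolerance for sample %s", b, rownames(spectra)[i] %||% i)
    a <- mean(x) - b * mean(reference)
    out[i, ] <- (x - a) / b
  }
  attr(out, "msc_reference") <- reference
  out
}

#' Savitzky-Golay smoothing
#'
#' Replaces each point by the value at that point of the least-squares
#' polynomial of degree `polyorder` fit over the centered window. Edge
#' points, where no centered window exists, take the fitted values of the
#' polynomial of the nearest full window (the usual "interp" edge mode).
#'
#' @param x numeric vector.
#' @param window odd window length, `3 <= window <= length(x)`.
#' @param polyorder polynomial degree, `polyorder < window`.
#' @return smoothed vector, same length as `x`.
#' @export
sg_smooth <- function(x, window = 11, polyorder = 2) {
  n <- length(x)
  if (window %% 2 != 1 || window < 3) stopf("window must be odd and >= 3")
  if (window > n) stopf("window (%d) exceeds signal length (%d)", window, n)
  if (polyorder >= window) stopf("polyorder must be below window")
  if (polyorder < 0) stopf("polyorder must be >= 0")
  h <- (window - 1L) %/% 2L
  A <- outer(seq(-h, h), 0:polyorder, `^`)
  # P y = fitted values of the windowed polynomial at the window points
  P <- A %*% solve(crossprod(A), t(A))
  w <- P[h + 1L, ]
  out <- as.numeric(stats::filter(x, w, sides = 2))
  out[1:h] <- (P %*% x[1:window])[1:h]
  out[(n - h + 1L):n] <- (P %*% x[(n - window + 1L):n])[(window - h + 1L):window]
  out
}

#' Apply a pretreatment to a spectrum set
#'
#' @param ss a [spectrum_set()].
#' @param method one of `"none"`, `"sg"`, `"msc"`, `"snv"`.
#' @param sg_window,sg_polyorder Savitzky-Golay parameters.
#' @param msc_reference reference spectrum for MSC; `NULL` fits the mean of
#'   `ss` (use the training-set reference for held-out spectra).
#' @return pretreated [spectrum_set()]; for MSC the reference used is
#'   attached as attribute `msc_reference`.
#' @export
preprocess_spectra <- function(ss, method = c("none", "sg", "msc", "snv"),
                               sg_window = 11, sg_polyorder = 2,
                               msc_reference = NULL) {
  stopifnot(inherits(ss, "spectrum_set"))
  method <- match.arg(method)
  X <- ss$spectra
  ref <- NULL
  if (method == "snv") {
    X <- snv(X)
  } else if (method == "msc") {
    X <- msc(X, reference = msc_reference)
    ref <- attr(X, "msc_reference")
  } else if (method == "sg") {
    for (i in seq_len(nrow(X))) X[i, ] <- sg_smooth(X[i, ], sg_window, sg_polyorder)
  }
  out <- spectrum_set(X, ss$wavelengths_nm, ss$labels, ss$sample_ids)
  attr(out, "msc_reference") <- ref
  attr(out, "pretreatment") <- method
  out
}
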