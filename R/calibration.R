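# Black/white calibration, band cropping, ROI mean spectra, and the
# SpectrumSet container.

#' Spectrum-set container
#'
#' Mean ROI transmittance spectra: one row per sample, one column per band.
#'
#' @param spectra n x B numeric matrix.
#' @param wavelengths_nm length-B increasing band axis.
#' @param labels integer class labels, one per row.
#' @param sample_ids character ids, one per row.
#' @return a `spectrum_set` list.
#' @export
spectrum_set <- function(spectra, wavelengths_nm, labels, sample_ids = NULL) {
  spectra <- as.matrix(spectra)
  if (ncol(spectra) != length(wavelengths_nm))
    stopf("spectra have %d columns but %d wavelengths", ncol(spectra), length(wavelengths_nm))
  if (is.unsorted(wavelengths_nm, strictly = TRUE))
    stopf("wavelengths must be strictly increasing")
  check_finite(spectra, "spectra")
  labels <- as.integer(labels)
  if (length(labels) != nrow(spectra)) stopf("one label per spectrum required")
  sample_ids <- sample_ids %||% sprintf("s%03d", seq_len(nrow(spectra)))
  if (length(sample_ids) != nrow(spectra)) stopf("one id per spectrum required")
  rownames(spectra) <- sample_ids
  structure(list(spectra = spectra, wavelengths_nm = as.numeric(wavelengths_nm),
                 labels = labels, sample_ids = as.character(sample_ids)),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra x %d bands (%.1f-%.1f nm), classes: %s\n",
              nrow(x$spectra), ncol(x$spectra),
              min(x$wavelengths_nm), max(x$wavelengths_nm),
              paste(sort(unique(x$labels)), collapse = " ")))
  invisible(x)
}

# Subset rows of a spectrum_set, keeping metadata aligned.
#' @export
subset_spectra <- function(ss, idx) {
  stopifnot(inherits(ss, "spectrum_set"))
  spectrum_set(ss$spectra[idx, , drop = FALSE], ss$wavelengths_nm,
               ss$labels[idx], ss$sample_ids[idx])
}

#' Black-and-white correction of a raw cube
#'
#' Converts raw sensor counts to transmittance,
#' `R = (I_raw - I_dark) / (I_ref - I_dark)` elementwise, using per-pixel
#' per-band white and dark reference frames. Pixels whose reference
#' difference is below `epsilon` in magnitude are flagged and set to 0; more
#' than 1% of such pixels is an error. Output is clipped to
#' `[0, clip_max]` (raw counts can exceed the white reference under noise).
#'
#' @param x an `hsi_sample`, or a raw H x W x B array.
#' @param ... passed to methods.
#' @return an `hsi_cube`: list with `transmittance` (H x W x B) and
#'   `wavelengths_nm`; attribute `degenerate` holds flagged element indices.
#' @export
calibrate <- function(x, ...) UseMethod("calibrate")

#' @rdname calibrate
#' @param white,dark reference arrays with the shape of the raw cube.
#' @param wavelengths_nm band axis (length = 3rd dimension).
#' @param epsilon positive threshold on |white - dark|.
#' @param clip_max upper clip for the transmittance output.
#' @export
calibrate.default <- function(x, white, dark, wavelengths_nm = NULL,
                              epsilon = 1e-6, clip_max = 2, ...) {
  raw <- x
  if (!identical(dim(raw), dim(white)) || !identical(dim(raw), dim(dark)))
    stopf("raw/white/dark shapes disagree")
  if (epsilon <= 0) stopf("epsilon must be positive")
  check_finite(raw, "raw cube")
  denom <- white - dark
  bad <- which(abs(denom) < epsilon)
  if (length(bad) > 0.01 * length(denom))
    stopf("%d of %d reference elements are denominator-degenerate (|white - dark| < %g)",
          length(bad), length(denom), epsilon)
  denom[bad] <- 1
  tr <- (raw - dark) / denom
  tr[bad] <- 0
  tr[tr < 0] <- 0
  tr[tr > clip_max] <- clip_max
  wavelengths_nm <- wavelengths_nm %||% seq_len(dim(raw)[3])
  out <- structure(list(transmittance = tr,
                        wavelengths_nm = as.numeric(wavelengths_nm)),
                   class = "hsi_cube")
  attr(out, "degenerate") <- bad
  out
}

#' @rdname calibrate
#' @export
calibrate.hsi_sample <- function(x, epsilon = 1e-6, clip_max = 2, ...) {
  calibrate.default(x$raw, x$white, x$dark, x$wavelengths_nm,
                    epsilon = epsilon, clip_max = clip_max)
}

#' Crop to an analysis wavelength window
#'
#' Keeps bands with `low_nm <= wavelength <= high_nm` (inclusive on both
#' bounds). On the default synthetic axis (401-1046 nm, 360 evenly spaced
#' bands) the default window keeps 334 bands; spectrograph axes that are not
#' perfectly uniform can keep a slightly different count for the same
#' nominal window.
#'
#' @param x an `hsi_cube` or [spectrum_set()].
#' @param low_nm,high_nm window bounds, `low_nm < high_nm`.
#' @return object of the same kind restricted to the window.
#' @export
crop_bands <- function(x, low_nm = 400, high_nm = 1000) UseMethod("crop_bands")

crop_keep_idx <- function(wl, low_nm, high_nm) {
  if (low_nm >= high_nm) stopf("low_nm must be below high_nm")
  keep <- which(wl >= low_nm & wl <= high_nm)
  if (length(keep) == 0) stopf("no bands inside [%g, %g] nm", low_nm, high_nm)
  if (length(keep) < 2) stopf("fewer than 2 bands inside [%g, %g] nm", low_nm, high_nm)
  keep
}

#' @export
crop_bands.hsi_cube <- function(x, low_nm = 400, high_nm = 1000) {
  keep <- crop_keep_idx(x$wavelengths_nm, low_nm, high_nm)
  out <- structure(list(transmittance = x$transmittance[, , keep, drop = FALSE],
                        wavelengths_nm = x$wavelengths_nm[keep]),
                   class = "hsi_cube")
  attr(out, "kept_bands") <- keep
  out
}

#' @export
crop_bands.spectrum_set <- function(x, low_nm = 400, high_nm = 1000) {
  keep <- crop_keep_idx(x$wavelengths_nm, low_nm, high_nm)
  out <- spectrum_set(x$spectra[, keep, drop = FALSE], x$wavelengths_nm[keep],
                      x$labels, x$sample_ids)
  attr(out, "kept_bands") <- keep
  out
}

#' Mean ROI spectrum of a transmittance cube
#'
#' Per-band arithmetic mean of the cube over the masked pixels.
#'
#' @param cube an `hsi_cube`.
#' @param mask logical H x W matrix with at least one `TRUE` pixel.
#' @return numeric vector of length B.
#' @export
roi_mean_spectrum <- function(cube, mask) {
  stopifnot(inherits(cube, "hsi_cube"))
  d <- dim(cube$transmittance)
  if (!identical(dim(mask), d[1:2])) stopf("mask shape does not match the cube")
  mv <- as.vector(mask)
  if (!any(mv)) stopf("empty ROI mask")
  m <- matrix(cube$transmittance, d[1] * d[2], d[3])
  colMeans(m[mv, , drop = FALSE])
}

#' Write / read a spectrum set as CSV
#'
#' Layout: first column `id`, second `label`, remaining columns named by
#' wavelength (`wl_<nm>`).
#'
#' @param ss a [spectrum_set()].
#' @param path CSV path.
#' @return `path` (write) or a [spectrum_set()] (read).
#' @export
write_spectrum_set <- function(ss, path) {
  stopifnot(inherits(ss, "spectrum_set"))
  df <- data.frame(id = ss$sample_ids, label = ss$labels,
                   ss$spectra, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[-(1:2)] <- sprintf("wl_%.4f", ss$wavelengths_nm)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_set
#' @export
read_spectrum_set <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  wl <- as.numeric(sub("^wl_", "", names(df)[-(1:2)]))
  spectrum_set(as.matrix(df[, -(1:2), drop = FALSE]), wl, df$label, df$id)
}
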