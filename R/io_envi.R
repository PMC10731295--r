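# ENVI cube I/O (header + flat binary) and 8-bit mask images.
#
# Supports BSQ/BIL/BIP interleaves, byte order from the header, data types
# 4 (float32) and 5 (float64). Cubes are H (lines) x W (samples) x B (bands)
# arrays in R.

#' Write a cube as an ENVI header + binary pair
#'
#' @param cube H x W x B numeric array.
#' @param prefix path prefix; writes `<prefix>.hdr` and `<prefix>.raw`.
#' @param wavelengths_nm optional band axis stored in the header.
#' @param interleave `"bsq"`, `"bil"`, or `"bip"`.
#' @param data_type ENVI data type code: 4 (float32) or 5 (float64).
#' @param byte_order 0 (little-endian) or 1 (big-endian).
#' @return `prefix`, invisibly.
#' @export
write_envi <- function(cube, prefix, wavelengths_nm = NULL,
                       interleave = c("bsq", "bil", "bip"),
                       data_type = 4, byte_order = 0) {
  interleave <- match.arg(interleave)
  if (length(dim(cube)) != 3) stopf("cube must be a 3-d array")
  if (!data_type %in% c(4, 5)) stopf("data_type must be 4 (float32) or 5 (float64)")
  d <- dim(cube)  # lines, samples, bands
  perm <- switch(interleave,
                 bsq = c(2, 1, 3),   # sample, line, band
                 bil = c(2, 3, 1),   # sample, band, line
                 bip = c(3, 2, 1))   # band, sample, line
  vals <- as.vector(aperm(cube, perm))
  hdr <- c("ENVI",
           sprintf("samples = %d", d[2]),
           sprintf("lines = %d", d[1]),
           sprintf("bands = %d", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           sprintf("data type = %d", data_type),
           sprintf("interleave = %s", interleave),
           sprintf("byte order = %d", byte_order))
  if (!is.null(wavelengths_nm)) {
    hdr <- c(hdr, "wavelength units = nm",
             sprintf("wavelength = { %s }",
                     paste(sprintf("%.6f", wavelengths_nm), collapse = ", ")))
  }
  writeLines(hdr, paste0(prefix, ".hdr"))
  con <- file(paste0(prefix, ".raw"), "wb")
  on.exit(close(con))
  writeBin(vals, con, size = if (data_type == 4) 4L else 8L,
           endian = if (byte_order == 0) "little" else "big")
  invisible(prefix)
}

parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  get_field <- function(name, required = TRUE) {
    m <- regmatches(txt, regexec(
      paste0("(?im)^\\s*", name, "\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"), txt, perl = TRUE))[[1]]
    if (length(m) < 2) {
      if (required) stopf("ENVI header missing field '%s'", name)
      return(NULL)
    }
    trimws(m[2])
  }
  out <- list(samples = as.integer(get_field("samples")),
              lines = as.integer(get_field("lines")),
              bands = as.integer(get_field("bands")),
              data_type = as.integer(get_field("data type")),
              interleave = tolower(get_field("interleave")),
              byte_order = as.integer(get_field("byte order", required = FALSE) %||% "0"),
              offset = as.integer(get_field("header offset", required = FALSE) %||% "0"))
  wl <- get_field("wavelength", required = FALSE)
  if (!is.null(wl)) {
    wl <- gsub("[{}]", "", wl)
    out$wavelengths_nm <- as.numeric(strsplit(wl, ",")[[1]])
  }
  out
}

#' Read an ENVI cube
#'
#' @param prefix path prefix (expects `<prefix>.hdr` and `<prefix>.raw`), or
#'   the path of the `.hdr` file itself.
#' @return list with `cube` (H x W x B array) and `wavelengths_nm`
#'   (`NULL` when the header has none).
#' @export
read_envi <- function(prefix) {
  hdr_path <- if (grepl("\\.hdr$", prefix)) prefix else paste0(prefix, ".hdr")
  raw_path <- sub("\\.hdr$", ".raw", hdr_path)
  if (!grepl("\\.hdr$", prefix)) raw_path <- paste0(prefix, ".raw")
  h <- parse_envi_header(hdr_path)
  if (!h$data_type %in% c(4L, 5L)) stopf("unsupported ENVI data type %d", h$data_type)
  n <- h$samples * h$lines * h$bands
  con <- file(raw_path, "rb")
  on.exit(close(con))
  if (h$offset > 0) readBin(con, "raw", h$offset)
  vals <- readBin(con, "double", n = n,
                  size = if (h$data_type == 4L) 4L else 8L,
                  endian = if (h$byte_order == 0L) "little" else "big")
  if (length(vals) != n) stopf("ENVI binary is truncated")
  cube <- switch(h$interleave,
                 bsq = aperm(array(vals, c(h$samples, h$lines, h$bands)), c(2, 1, 3)),
                 bil = aperm(array(vals, c(h$samples, h$bands, h$lines)), c(3, 1, 2)),
                 bip = aperm(array(vals, c(h$bands, h$samples, h$lines)), c(3, 2, 1)),
                 stopf("unsupported interleave '%s'", h$interleave))
  list(cube = cube, wavelengths_nm = h$wavelengths_nm)
}

#' Write / read a binary ROI mask as an 8-bit PNG
#'
#' Nonzero pixels are ROI.
#'
#' @param mask logical matrix.
#' @param path PNG path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0
}

#' Export a dataset as ENVI cubes + masks + manifest
#'
#' Writes each sample's raw cube as ENVI (`<id>.hdr`/`<id>.raw`), its ROI
#' mask as `<id>_mask.png`, and a `manifest.csv` with columns
#' `id,label,seed,path`.
#'
#' @param dataset an `hsi_dataset` from [generate_dataset()].
#' @param dir output directory (created if missing).
#' @param ... passed to [write_envi()].
#' @return the manifest data.frame, invisibly.
#' @export
export_dataset <- function(dataset, dir, ...) {
  stopifnot(inherits(dataset, "hsi_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- dataset$manifest
  man$path <- file.path(dir, man$id)
  for (i in seq_len(nrow(man))) {
    s <- dataset$samples[[i]]
    write_envi(s$raw, man$path[i], s$wavelengths_nm, ...)
    write_mask_png(s$roi_mask, paste0(man$path[i], "_mask.png"))
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
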