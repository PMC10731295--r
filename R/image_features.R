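# Per-sample image features from grayscale band images at the selected
# wavelengths, via a pluggable convolutional backend.
#
# The default backend ("seeded_conv") is a fixed-architecture, seeded,
# randomly initialized convolutional stack with global per-channel pooling
# statistics forming a 2048-dimensional descriptor. Random convolutional features are an accepted
# texture descriptor; the backend is fully deterministic given its seed and
# needs no downloaded weights. A "resnet50_pretrained" backend name is
# reserved for the pretrained pathway and errors when its weights are not
# installed.

#' Bilinear resize of a matrix image
#'
#' Align-corners convention: the four corner pixels of the input map exactly
#' onto the corners of the output.
#'
#' @param img numeric matrix.
#' @param out_h,out_w output size in pixels.
#' @return `out_h` x `out_w` matrix.
#' @export
bilinear_resize <- function(img, out_h, out_w) {
  h <- nrow(img); w <- ncol(img)
  src_axis <- function(n_in, n_out) {
    if (n_out == 1) return(rep((n_in + 1) / 2, 1))
    1 + (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
  }
  sr <- src_axis(h, out_h)
  sc <- src_axis(w, out_w)
  r0 <- pmin(floor(sr), h - 1L); fr <- sr - r0
  c0 <- pmin(floor(sc), w - 1L); fc <- sc - c0
  if (h == 1) { r0 <- rep(1L, out_h); fr <- rep(0, out_h) }
  if (w == 1) { c0 <- rep(1L, out_w); fc <- rep(0, out_w) }
  img[r0, c0, drop = FALSE] * ((1 - fr) %o% (1 - fc)) +
    img[pmin(r0 + 1, h), c0, drop = FALSE] * (fr %o% (1 - fc)) +
    img[r0, pmin(c0 + 1, w), drop = FALSE] * ((1 - fr) %o% fc) +
    img[pmin(r0 + 1, h), pmin(c0 + 1, w), drop = FALSE] * (fr %o% fc)
}

#' Prepare a band image for the feature backend
#'
#' Center-crops to the largest centered square, resizes to
#' `out_size` x `out_size` by bilinear interpolation, min-max normalizes to
#' [0, 1] per image (a constant image maps to all zeros), and replicates the
#' single channel to three.
#'
#' @param image numeric matrix (H, W >= 8).
#' @param out_size output side length, pixels.
#' @return `out_size` x `out_size` x 3 array with identical channels.
#' @export
prepare_image <- function(image, out_size = 224) {
  if (!is.matrix(image)) stopf("image must be a matrix")
  if (any(!is.finite(image))) stopf("non-finite pixels in image")
  h <- nrow(image); w <- ncol(image)
  if (h < 8 || w < 8) stopf("image must be at least 8x8")
  side <- min(h, w)
  r0 <- (h - side) %/% 2L
  c0 <- (w - side) %/% 2L
  crop <- image[(r0 + 1L):(r0 + side), (c0 + 1L):(c0 + side), drop = FALSE]
  res <- bilinear_resize(crop, out_size, out_size)
  rng <- range(res)
  if (diff(rng) < 1e-12) res[] <- 0 else res <- (res - rng[1]) / diff(rng)
  array(res, dim = c(out_size, out_size, 3L))
}

# seeded_conv architecture: kernel size / stride / channels per layer. The
# 512 final channels are pooled globally with four statistics per channel
# (mean, max, sd, rms) -> 2048 features. Global pooling makes the
# descriptor invariant to where filaments lie in the frame, so it measures
# texture (width, edge density) rather than layout.
seeded_conv_layers <- function() {
  list(list(k = 7L, stride = 4L, cin = 3L,  cout = 32L),
       list(k = 5L, stride = 3L, cin = 32L, cout = 96L),
       list(k = 3L, stride = 2L, cin = 96L, cout = 512L))
}

#' Construct an image feature backend
#'
#' @param name `"seeded_conv"` (default, deterministic, no external weights)
#'   or `"resnet50_pretrained"` (errors unless pretrained weights are
#'   installed, with instructions to fall back to the seeded backend).
#' @param seed seed for the random He-scaled initialization.
#' @param feature_dim output dimensionality; the seeded architecture is
#'   fixed at 2048 (512 channels x 4 global pooling statistics).
#' @param out_size input side length fed to the stack; must leave a final
#'   feature map of at least 2 x 2 (>= 71 pixels; the default 224 gives an
#'   8 x 8 map).
#' @return a `feature_backend` with the seeded weight matrices attached.
#' @export
feature_backend <- function(name = c("seeded_conv", "resnet50_pretrained"),
                            seed = 42, feature_dim = 2048, out_size = 224) {
  name <- match.arg(name)
  if (name == "resnet50_pretrained")
    stopf(paste("resnet50_pretrained backend: pretrained weights are not",
                "installed; use feature_backend(\"seeded_conv\") instead"))
  layers <- seeded_conv_layers()
  if (feature_dim != 512L * 4L)
    stopf("seeded_conv produces %d-dimensional features", 512L * 4L)
  s <- out_size
  for (L in layers) s <- (s - L$k) %/% L$stride + 1L
  if (s < 2L) stopf("out_size %d leaves a %dx%d final map; need >= 2x2", out_size, s, s)
  weights <- with_seed(seed, lapply(layers, function(L) {
    fan_in <- L$k * L$k * L$cin
    matrix(rnorm(fan_in * L$cout, sd = sqrt(2 / fan_in)), fan_in, L$cout)
  }))
  structure(list(name = name, seed = as.integer(seed),
                 feature_dim = as.integer(feature_dim),
                 out_size = as.integer(out_size),
                 deterministic = TRUE,
                 layers = layers, weights = weights),
            class = "feature_backend")
}

# im2col convolution + ReLU. x: h x w x cin array; W: (k*k*cin) x cout.
conv_relu <- function(x, W, k, stride) {
  h <- dim(x)[1]; w <- dim(x)[2]; cin <- dim(x)[3]
  oh <- (h - k) %/% stride + 1L
  ow <- (w - k) %/% stride + 1L
  ri <- (seq_len(oh) - 1L) * stride
  ci <- (seq_len(ow) - 1L) * stride
  # flat-index gather: patch rows are (position), columns (di, dj, channel)
  base <- outer(ri + 1L, ci * h, `+`)                       # oh x ow
  off <- outer(seq_len(k) - 1L, (seq_len(k) - 1L) * h, `+`) # k x k
  off <- outer(as.vector(off), (seq_len(cin) - 1L) * (h * w), `+`)
  P <- matrix(x[outer(as.vector(base), as.vector(off), `+`)],
              oh * ow, k * k * cin)
  out <- P %*% W
  out[out < 0] <- 0
  array(out, dim = c(oh, ow, ncol(W)))
}

# Global per-channel pooling statistics: mean, max, sd, root-mean-square.
global_pool_stats <- function(x) {
  nc <- dim(x)[3]
  m <- matrix(x, prod(dim(x)[1:2]), nc)
  c(colMeans(m),
    apply(m, 2, max),
    apply(m, 2, stats::sd),
    sqrt(colMeans(m^2)))
}

#' Feature vector of one prepared image
#'
#' @param backend a [feature_backend()].
#' @param image3 `out_size` x `out_size` x 3 array from [prepare_image()].
#' @return numeric vector of length `backend$feature_dim`.
#' @export
backend_features <- function(backend, image3) {
  stopifnot(inherits(backend, "feature_backend"))
  x <- image3
  for (i in seq_along(backend$layers)) {
    L <- backend$layers[[i]]
    x <- conv_relu(x, backend$weights[[i]], L$k, L$stride)
  }
  global_pool_stats(x)
}

#' Extract per-sample image features from band-image stacks
#'
#' Each band image of a sample is prepared ([prepare_image()]) and passed
#' through the backend; the per-band feature vectors are aggregated into one
#' vector per sample (default: mean, which keeps the backend dimensionality).
#'
#' @param band_images list with one element per sample: an H x W x n_bands
#'   array (or a list of H x W matrices).
#' @param backend a [feature_backend()].
#' @param aggregate `"mean"` or `"max"` across the band images of a sample.
#' @param labels,sample_ids optional per-sample metadata carried through.
#' @return a `feature_matrix`: list with `features` (n x feature_dim),
#'   `sample_ids`, `labels`, `aggregate`, `backend_name`.
#' @export
extract_features <- function(band_images, backend, aggregate = c("mean", "max"),
                             labels = NULL, sample_ids = NULL) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(backend, "feature_backend"))
  if (length(band_images) == 0) stopf("empty image stack")
  feats <- matrix(NA_real_, length(band_images), backend$feature_dim)
  for (i in seq_along(band_images)) {
    s <- band_images[[i]]
    imgs <- if (is.list(s)) s else lapply(seq_len(dim(s)[3]), function(b) s[, , b])
    fb <- vapply(imgs, function(im) {
      backend_features(backend, prepare_image(im, backend$out_size))
    }, numeric(backend$feature_dim))
    feats[i, ] <- if (aggregate == "mean") rowMeans(fb) else apply(fb, 1, max)
  }
  check_finite(feats, "image features")
  structure(list(features = feats,
                 sample_ids = sample_ids %||% sprintf("s%03d", seq_len(nrow(feats))),
                 labels = labels, aggregate = aggregate,
                 backend_name = backend$name),
            class = "feature_matrix")
}
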