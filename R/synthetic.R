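# Synthetic micro-hyperspectral scene generator.
#
# Emulates transmittance imaging of growing mycelium: filaments are smooth
# random paths rasterized with a Gaussian cross-profile; per-pixel
# transmittance blends a mycelium endmember and a background (agar medium)
# endmember by the filament coverage fraction; raw sensor counts are
# reconstructed from per-pixel white/dark reference frames with additive
# Gaussian noise and per-sample multiplicative-scatter / additive-baseline
# distortions (the distortions SNV and MSC are meant to remove).

gaussian_bump <- function(x, center, width) exp(-((x - center)^2) / (2 * width^2))

# Smooth endmember transmittance of the uninoculated medium: the agar is
# near-transparent and spectrally almost flat over 400-1050 nm, with only a
# faint broad tint and a weak NIR water dip.
endmember_background_curve <- function(wavelengths_nm) {
  t <- 0.92 +
    0.015 * gaussian_bump(wavelengths_nm, 550, 150) -
    0.010 * gaussian_bump(wavelengths_nm, 970, 80)
  pmin(pmax(t, 0.05), 1.2)
}

# Base mycelium endmember: lower transmittance than the medium, with shared
# peak/valley structure (pigment band in the blue, weak red dip, NIR water
# band) that all degradation classes inherit.
endmember_mycelium_curve <- function(wavelengths_nm) {
  t <- 0.66 +
    0.10 * gaussian_bump(wavelengths_nm, 540, 90) -
    0.22 * gaussian_bump(wavelengths_nm, 470, 45) -
    0.15 * gaussian_bump(wavelengths_nm, 670, 40) -
    0.18 * gaussian_bump(wavelengths_nm, 960, 45) +
    0.05 * gaussian_bump(wavelengths_nm, 820, 80)
  pmin(pmax(t, 0.05), 1.2)
}

#' Degradation-class profile
#'
#' Describes one degradation grade: mean/sd filament width in pixels, a
#' transmittance offset (more degraded mycelium transmits slightly more
#' light), and the two endmember transmittance curves on the band axis.
#'
#' @param label integer class label (0 = undegraded ... 3 = most degraded).
#' @param filament_width_px mean filament width (full width at half maximum
#'   of the Gaussian cross-profile), pixels.
#' @param filament_width_sd standard deviation of per-filament width, pixels.
#' @param transmittance_offset dimensionless shift of the mycelium endmember
#'   toward the bright ceiling; increases with degradation.
#' @param endmember_mycelium,endmember_background transmittance curves over
#'   the band axis, values in (0, 1.2].
#' @return a `class_profile` list.
#' @export
class_profile <- function(label, filament_width_px, filament_width_sd,
                          transmittance_offset,
                          endmember_mycelium, endmember_background) {
  label <- as.integer(label)
  if (filament_width_px <= 0) stopf("filament_width_px must be positive")
  if (filament_width_sd < 0) stopf("filament_width_sd must be >= 0")
  for (nm in c("endmember_mycelium", "endmember_background")) {
    e <- get(nm)
    if (any(e <= 0) || any(e > 1.2)) stopf("%s must lie in (0, 1.2]", nm)
  }
  structure(
    list(label = label,
         filament_width_px = filament_width_px,
         filament_width_sd = filament_width_sd,
         transmittance_offset = transmittance_offset,
         endmember_mycelium = endmember_mycelium,
         endmember_background = endmember_background),
    class = "class_profile")
}

#' Default four-class degradation profiles
#'
#' Widths decrease and transmittance offsets increase strictly with the
#' degradation label. `class_contrast` scales both differences about their
#' across-class mean; 0 collapses all classes onto one phenotype (a null
#' configuration for chance-level checks).
#'
#' @param wavelengths_nm band axis.
#' @param class_contrast non-negative multiplier on between-class differences.
#' @return list of four [class_profile()]s, labels 0-3.
#' @export
default_class_profiles <- function(wavelengths_nm, class_contrast = 1) {
  if (class_contrast < 0) stopf("class_contrast must be >= 0")
  base_w <- c(9, 7.5, 6, 4.5)
  base_off <- c(0, 0.06, 0.12, 0.18)
  w <- mean(base_w) + class_contrast * (base_w - mean(base_w))
  off <- mean(base_off) + class_contrast * (base_off - mean(base_off))
  bg <- endmember_background_curve(wavelengths_nm)
  myc0 <- endmember_mycelium_curve(wavelengths_nm)
  # Degradation raises transmittance overall, fades the pigment band near
  # 470 nm faster than proportionally, and slightly deepens the relative
  # NIR water band: thinner, less pigmented hyphae.
  pigment <- gaussian_bump(wavelengths_nm, 470, 45)
  water <- gaussian_bump(wavelengths_nm, 960, 45)
  lapply(0:3, function(l) {
    o <- off[l + 1]
    myc <- myc0 + o * (1.05 - myc0) + o * 0.6 * pigment - o * 0.35 * water
    class_profile(
      label = l,
      filament_width_px = w[l + 1],
      filament_width_sd = 0.8,
      transmittance_offset = o,
      endmember_mycelium = pmin(pmax(myc, 0.02), 1.2),
      endmember_background = bg)
  })
}

#' Scene configuration for the synthetic generator
#'
#' @param image_height,image_width scene size, pixels.
#' @param n_bands number of spectral bands (>= 2).
#' @param wavelength_start_nm,wavelength_end_nm band axis endpoints; bands
#'   are evenly spaced at (end - start)/(n_bands - 1).
#' @param class_contrast multiplier on between-class phenotype differences
#'   used when `classes` is built by default; see [default_class_profiles()].
#' @param classes list of [class_profile()]s with distinct labels.
#' @param filaments_per_image integer range `c(min, max)` of filament count.
#' @param noise_sd additive Gaussian sensor noise, transmittance units.
#' @param baseline_drift_sd sd of the per-sample additive baseline offset.
#' @param scatter_slope_sd sd of the per-sample multiplicative scatter slope
#'   about 1.
#' @param white_level,dark_level reference frame intensity levels (sensor
#'   counts); `white_level` must exceed `dark_level`.
#' @param reference_shading logical; apply a smooth vignette and lamp
#'   spectrum to the white frame (TRUE) or use flat references (FALSE).
#' @return a `scene_config` list with the wavelength axis attached.
#' @export
scene_config <- function(image_height = 128, image_width = 128,
                         n_bands = 360,
                         wavelength_start_nm = 401, wavelength_end_nm = 1046,
                         class_contrast = 1,
                         classes = NULL,
                         filaments_per_image = c(3, 6),
                         noise_sd = 0.005,
                         baseline_drift_sd = 0.02,
                         scatter_slope_sd = 0.05,
                         white_level = 3000, dark_level = 100,
                         reference_shading = TRUE) {
  if (n_bands < 2) stopf("n_bands must be >= 2")
  if (wavelength_end_nm <= wavelength_start_nm) stopf("wavelength axis must increase")
  if (noise_sd < 0 || baseline_drift_sd < 0 || scatter_slope_sd < 0)
    stopf("noise and distortion sds must be >= 0")
  if (white_level <= dark_level) stopf("white_level must exceed dark_level")
  if (image_height < 8 || image_width < 8) stopf("scene must be at least 8x8 pixels")
  wl <- seq(wavelength_start_nm, wavelength_end_nm, length.out = n_bands)
  if (is.null(classes)) classes <- default_class_profiles(wl, class_contrast)
  labs <- vapply(classes, `[[`, integer(1), "label")
  if (length(labs) == 0 || anyDuplicated(labs)) stopf("classes must be non-empty with distinct labels")
  o <- order(labs)
  classes <- classes[o]
  wms <- vapply(classes, `[[`, numeric(1), "filament_width_px")
  offs <- vapply(classes, `[[`, numeric(1), "transmittance_offset")
  if (length(classes) > 1) {
    if (any(diff(wms) > 0) || any(diff(offs) < 0))
      stopf("width means must be non-increasing and offsets non-decreasing in the label")
    if (class_contrast > 0 && (any(diff(wms) >= 0) || any(diff(offs) <= 0)))
      stopf("width means must strictly decrease and offsets strictly increase with the label")
  }
  for (p in classes) {
    if (length(p$endmember_mycelium) != n_bands ||
        length(p$endmember_background) != n_bands)
      stopf("endmember curves must have length n_bands")
  }
  structure(
    list(image_height = image_height, image_width = image_width,
         n_bands = n_bands, wavelengths_nm = wl,
         class_contrast = class_contrast, classes = classes,
         filaments_per_image = as.integer(filaments_per_image),
         noise_sd = noise_sd, baseline_drift_sd = baseline_drift_sd,
         scatter_slope_sd = scatter_slope_sd,
         white_level = white_level, dark_level = dark_level,
         reference_shading = reference_shading),
    class = "scene_config")
}

# One filament: a persistent-direction random walk entering from a random
# image edge. Returns an m x 2 matrix of (x, y) vertices.
random_filament_path <- function(h, w, step = 3, turn_sd = 0.15, max_steps = 400) {
  edge <- sample.int(4, 1)
  u <- runif(1)
  if (edge == 1L) { x <- u * w; y <- 0;     ang <- runif(1,  pi / 4,  3 * pi / 4) }
  if (edge == 2L) { x <- u * w; y <- h;     ang <- runif(1, -3 * pi / 4, -pi / 4) }
  if (edge == 3L) { x <- 0;     y <- u * h; ang <- runif(1, -pi / 4,  pi / 4) }
  if (edge == 4L) { x <- w;     y <- u * h; ang <- runif(1,  3 * pi / 4, 5 * pi / 4) }
  pts <- matrix(NA_real_, max_steps + 1L, 2L)
  pts[1L, ] <- c(x, y)
  n <- 1L
  for (i in seq_len(max_steps)) {
    ang <- ang + rnorm(1, 0, turn_sd)
    x <- x + step * cos(ang)
    y <- y + step * sin(ang)
    n <- n + 1L
    pts[n, ] <- c(x, y)
    if (x < -0.2 * w || x > 1.2 * w || y < -0.2 * h || y > 1.2 * h) break
  }
  pts[seq_len(n), , drop = FALSE]
}

# Squared distance from every pixel center inside a padded segment bounding
# box to the segment; accumulated into `mind2` (an h x w matrix).
update_segment_dist2 <- function(mind2, p1, p2, pad, h, w) {
  r0 <- max(1L, floor(min(p1[2], p2[2]) - pad))
  r1 <- min(h, ceiling(max(p1[2], p2[2]) + pad))
  c0 <- max(1L, floor(min(p1[1], p2[1]) - pad))
  c1 <- min(w, ceiling(max(p1[1], p2[1]) + pad))
  if (r0 > r1 || c0 > c1) return(mind2)
  rows <- r0:r1; cols <- c0:c1
  Y <- matrix(rows, length(rows), length(cols))
  X <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
  l2 <- vx * vx + vy * vy
  if (l2 < 1e-12) {
    dx <- X - p1[1]; dy <- Y - p1[2]
  } else {
    t <- ((X - p1[1]) * vx + (Y - p1[2]) * vy) / l2
    t[t < 0] <- 0; t[t > 1] <- 1
    dx <- X - (p1[1] + t * vx)
    dy <- Y - (p1[2] + t * vy)
  }
  d2 <- dx * dx + dy * dy
  mind2[rows, cols] <- pmin(mind2[rows, cols], d2)
  mind2
}

# Rasterize filaments with a Gaussian cross-profile. Coverage of overlapping
# filaments composes as 1 - prod(1 - c_i), staying in [0, 1).
filament_coverage <- function(h, w, paths, widths_px) {
  comp <- matrix(1, h, w)
  for (f in seq_along(paths)) {
    sigma <- widths_px[f] / (2 * sqrt(2 * log(2)))  # width = FWHM
    pad <- ceiling(3.5 * sigma) + 1
    pts <- paths[[f]]
    mind2 <- matrix(Inf, h, w)
    for (s in seq_len(nrow(pts) - 1L)) {
      mind2 <- update_segment_dist2(mind2, pts[s, ], pts[s + 1L, ], pad, h, w)
    }
    comp <- comp * (1 - exp(-mind2 / (2 * sigma^2)))
  }
  1 - comp
}

# Smooth illumination (vignette) field in [0.75, 1].
illumination_field <- function(h, w) {
  yy <- (seq_len(h) - (h + 1) / 2) / (h / 2)
  xx <- (seq_len(w) - (w + 1) / 2) / (w / 2)
  1 - 0.125 * (outer(yy^2, rep(1, w)) + outer(rep(1, h), xx^2))
}

lamp_spectrum <- function(wavelengths_nm) {
  0.65 + 0.35 * gaussian_bump(wavelengths_nm, 650, 260)
}

#' Generate one synthetic micro-hyperspectral sample
#'
#' Builds the filament geometry, the per-pixel transmittance field (endmember
#' blend by coverage, then per-sample scatter slope and baseline offset), the
#' white/dark reference frames, and the raw sensor cube
#' `raw = dark + (T + noise) * (white - dark)`. All randomness derives from
#' `seed`; the same `(config, label, seed)` reproduces the sample
#' bit-for-bit, and any `bands` subset reproduces exactly the corresponding
#' slices of the full cube.
#'
#' @param config a [scene_config()].
#' @param label class label; must match a configured [class_profile()].
#' @param seed integer sample seed.
#' @param bands optional integer vector of band indices to generate
#'   (defaults to all bands).
#' @return an `hsi_sample` list: `raw`, `white`, `dark` (H x W x B arrays),
#'   `wavelengths_nm`, `band_indices`, `roi_mask` (logical H x W, filament
#'   core pixels), `label`, and `truth` (the constructed transmittance field,
#'   coverage fraction, scatter slope/intercept, filament widths, profile).
#' @export
generate_sample <- function(config, label, seed, bands = NULL) {
  stopifnot(inherits(config, "scene_config"))
  labs <- vapply(config$classes, `[[`, integer(1), "label")
  ci <- match(as.integer(label), labs)
  if (is.na(ci)) stopf("unknown class label %s (configured: %s)",
                       label, paste(labs, collapse = ", "))
  prof <- config$classes[[ci]]
  h <- config$image_height; w <- config$image_width
  nb <- config$n_bands
  bands <- if (is.null(bands)) seq_len(nb) else as.integer(bands)
  if (any(bands < 1L | bands > nb)) stopf("band indices out of range")

  sub <- derive_seeds(seed, nb + 2L)
  geom_seed <- sub[1L]; dist_seed <- sub[2L]; band_seeds <- sub[-(1:2)]

  geom <- with_seed(geom_seed, {
    for (attempt in 1:25) {
      n_fil <- sample(config$filaments_per_image[1]:config$filaments_per_image[2], 1L)
      paths <- replicate(n_fil, random_filament_path(h, w), simplify = FALSE)
      widths <- pmax(1, rnorm(n_fil, prof$filament_width_px, prof$filament_width_sd))
      cov <- filament_coverage(h, w, paths, widths)
      mask <- cov >= 0.5
      if (sum(mask) >= 50L) break
    }
    if (sum(mask) < 50L) stopf("could not place >= 50 ROI pixels; scene too small")
    list(coverage = cov, mask = mask, widths = widths, n_filaments = n_fil)
  })

  dst <- with_seed(dist_seed, {
    list(slope = max(1 + rnorm(1, 0, config$scatter_slope_sd), 0.2),
         intercept = rnorm(1, 0, config$baseline_drift_sd))
  })

  k <- length(bands)
  covv <- as.vector(geom$coverage)
  myc <- prof$endmember_mycelium[bands]
  bgv <- prof$endmember_background[bands]
  tr <- outer(covv, myc - bgv)                        # (h*w) x k
  tr <- tr + rep(bgv, each = h * w)                   # blend: cov*myc + (1-cov)*bg
  tr <- dst$slope * tr + dst$intercept

  if (config$reference_shading) {
    illum <- as.vector(illumination_field(h, w))
    lamp <- lamp_spectrum(config$wavelengths_nm)[bands]
  } else {
    illum <- rep(1, h * w)
    lamp <- rep(1, k)
  }
  white <- config$white_level * outer(illum, lamp)
  dark <- matrix(config$dark_level, h * w, k)
  if (any(white <= dark)) stopf("white frame must exceed dark frame everywhere")

  eff <- tr
  if (config$noise_sd > 0) {
    for (j in seq_len(k)) {
      eff[, j] <- eff[, j] +
        with_seed(band_seeds[bands[j]], rnorm(h * w, 0, config$noise_sd))
    }
  }
  raw <- dark + eff * (white - dark)

  dims <- c(h, w, k)
  dim(raw) <- dims; dim(white) <- dims; dim(dark) <- dims; dim(tr) <- dims
  structure(
    list(raw = raw,
         white = white,
         dark = dark,
         wavelengths_nm = config$wavelengths_nm[bands],
         band_indices = bands,
         roi_mask = geom$mask,
         label = prof$label,
         truth = list(transmittance = tr,
                      coverage = geom$coverage,
                      slope = dst$slope, intercept = dst$intercept,
                      widths_px = geom$widths,
                      n_filaments = geom$n_filaments,
                      profile = prof)),
    class = "hsi_sample")
}

#' Sample manifest for a balanced dataset
#'
#' @param config a [scene_config()].
#' @param n_per_class samples per class (>= 1).
#' @param seed master seed; per-sample seeds are derived reproducibly.
#' @return data.frame with columns `id`, `label`, `seed`.
#' @export
dataset_manifest <- function(config, n_per_class, seed) {
  stopifnot(inherits(config, "scene_config"))
  if (n_per_class < 1) stopf("n_per_class must be >= 1")
  labs <- vapply(config$classes, `[[`, integer(1), "label")
  labels <- rep(labs, each = n_per_class)
  n <- length(labels)
  data.frame(id = sprintf("s%03d", seq_len(n)),
             label = labels,
             seed = derive_seeds(seed, n),
             stringsAsFactors = FALSE)
}

#' Generate a balanced synthetic dataset
#'
#' Materializes every sample in memory; intended for small scenes. For the
#' desk-scale pipeline use [dataset_spectra()] / [dataset_band_images()],
#' which regenerate samples from the manifest instead of holding full cubes.
#'
#' @inheritParams dataset_manifest
#' @param bands optional band subset passed to [generate_sample()].
#' @return an `hsi_dataset`: list of `samples`, the `manifest`, and `config`.
#' @export
generate_dataset <- function(config, n_per_class, seed, bands = NULL) {
  manifest <- dataset_manifest(config, n_per_class, seed)
  samples <- lapply(seq_len(nrow(manifest)), function(i) {
    generate_sample(config, manifest$label[i], manifest$seed[i], bands = bands)
  })
  structure(list(samples = samples, manifest = manifest, config = config),
            class = "hsi_dataset")
}

#' Distance-transform estimate of mean filament width
#'
#' Computes the Euclidean distance transform of the ROI mask and returns
#' 4 x the mean foreground distance: for an ideal ribbon of width W the mean
#' distance to background is W/4, so the statistic estimates W.
#'
#' @param mask logical matrix of filament-core pixels.
#' @return estimated width, pixels.
#' @export
measure_filament_width <- function(mask) {
  if (!any(mask)) stopf("empty mask")
  dm <- EBImage::distmap(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  dm <- as.matrix(dm)
  4 * mean(dm[mask])
}

#' Spectrum matrix with planted informative bands
#'
#' Builds a spectrum-set whose integer labels are (quantized) linear in the
#' latent signals carried by three planted bands, on top of a smooth
#' low-rank baseline. Used to check that SPA + RMSE model sizing recovers a
#' known informative band subset.
#'
#' @param n_per_class samples per class (4 classes).
#' @param n_bands number of bands.
#' @param planted indices of the informative bands.
#' @param signal_sd amplitude of the planted latent signals.
#' @param noise_sd iid measurement noise added to every band.
#' @param seed integer seed.
#' @return a [spectrum_set()] with attribute `planted_bands`.
#' @export
planted_band_dataset <- function(n_per_class = 20, n_bands = 40,
                                 planted = c(5, 18, 32),
                                 signal_sd = 0.5, noise_sd = 0.02, seed = 1) {
  if (length(planted) != 3 || any(planted < 1 | planted > n_bands))
    stopf("planted must be 3 valid band indices")
  n <- 4L * n_per_class
  wl <- seq(401, 1046, length.out = n_bands)
  out <- with_seed(seed, {
    z <- matrix(rnorm(n * 3), n, 3)
    ycont <- rowSums(z)
    qs <- stats::quantile(ycont, probs = seq(0, 1, 0.25))
    labels <- as.integer(cut(ycont, qs, include.lowest = TRUE, labels = FALSE)) - 1L
    base <- 0.6 + 0.1 * gaussian_bump(wl, 600, 150)
    comp1 <- gaussian_bump(wl, 700, 200)
    comp2 <- gaussian_bump(wl, 500, 120)
    X <- rep(1, n) %o% base +
      rnorm(n, 0, 0.05) %o% comp1 +
      rnorm(n, 0, 0.05) %o% comp2 +
      matrix(rnorm(n * n_bands, 0, noise_sd), n, n_bands)
    X[, planted] <- X[, planted] + signal_sd * z
    list(X = X, labels = labels)
  })
  ss <- spectrum_set(out$X, wl, out$labels,
                     sample_ids = sprintf("p%03d", seq_len(n)))
  attr(ss, "planted_bands") <- as.integer(planted)
  ss
}
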