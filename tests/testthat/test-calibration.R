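make_refs <- function(h = 4, w = 4, b = 3, white = 120, dark = 20) {
  list(white = array(white, c(h, w, b)), dark = array(dark, c(h, w, b)))
}

test_that("black/white correction satisfies its endpoint identities", {
  r <- make_refs()
  expect_equal(calibrate(r$white, r$white, r$dark)$transmittance,
               array(1, dim(r$white)))
  expect_equal(calibrate(r$dark, r$white, r$dark)$transmittance,
               array(0, dim(r$white)))
  # single-cell direct evaluation: (80 - 20) / (120 - 20) = 0.6
  one <- calibrate(array(80, c(1, 1, 1)), array(120, c(1, 1, 1)),
                   array(20, c(1, 1, 1)))
  expect_equal(one$transmittance[1, 1, 1], 0.6)
})

test_that("calibration flags degenerate denominators and validates shapes", {
  r <- make_refs()
  expect_error(calibrate(r$white[, , 1:2], r$white, r$dark), "shapes")
  # > 1% degenerate pixels is an error naming the count
  bad_white <- r$white; bad_white[, , 1] <- r$dark[, , 1]
  expect_error(calibrate(r$white, bad_white, r$dark), "16 of 48")
  # a single degenerate cell (here 1/256 < 1%) is flagged and zeroed
  rbig <- make_refs(8, 8, 4)
  w1 <- rbig$white; w1[1, 1, 1] <- rbig$dark[1, 1, 1]
  raw <- rbig$dark + 0.5 * (w1 - rbig$dark)
  out <- calibrate(raw, w1, rbig$dark)
  expect_identical(attr(out, "degenerate"), 1L)
  expect_equal(out$transmittance[1, 1, 1], 0)
  expect_equal(out$transmittance[2, 1, 1], 0.5)
})

test_that("calibration clips to [0, clip_max] and is monotone in the raw counts", {
  r <- make_refs()
  hot <- r$white * 3
  expect_equal(max(calibrate(hot, r$white, r$dark)$transmittance), 2)
  cold <- r$dark - 50
  expect_equal(min(calibrate(cold, r$white, r$dark)$transmittance), 0)
  set.seed(2)
  a <- r$dark + array(runif(48, 0, 80), dim(r$dark))
  bump <- a + 5
  expect_true(all(calibrate(bump, r$white, r$dark)$transmittance >=
                    calibrate(a, r$white, r$dark)$transmittance))
})

test_that("zero-noise generator output calibrates back to the constructed field", {
  cfg <- small_scene(noise_sd = 0)
  for (lab in c(0, 2)) {
    s <- generate_sample(cfg, lab, seed = 31 + lab)
    cube <- calibrate(s)
    expect_lt(max(abs(cube$transmittance - s$truth$transmittance)), 1e-10)
  }
})

test_that("band cropping keeps the documented window", {
  cfg <- scene_config()  # default axis: 401-1046 nm, 360 bands
  wl <- cfg$wavelengths_nm
  ss <- spectrum_set(matrix(runif(2 * 360), 2), wl, c(0, 1))
  full <- crop_bands(ss, 401, 1046)
  expect_identical(ncol(full$spectra), 360L)
  win <- crop_bands(ss, 400, 1000)
  # inclusive bounds on the uniform synthetic axis: floor((1000-401)/step)+1
  step <- (1046 - 401) / 359
  expect_identical(ncol(win$spectra), as.integer(floor((1000 - 401) / step) + 1))
  expect_identical(ncol(win$spectra), 334L)
  expect_true(all(win$wavelengths_nm >= 400 & win$wavelengths_nm <= 1000))
  expect_error(crop_bands(ss, 500, 500.5), "bands inside")
  expect_error(crop_bands(ss, 700, 600), "low_nm")
})

test_that("ROI mean spectra average exactly over the masked pixels", {
  set.seed(5)
  cube <- structure(list(transmittance = array(runif(4 * 4 * 6), c(4, 4, 6)),
                         wavelengths_nm = 1:6), class = "hsi_cube")
  m1 <- matrix(FALSE, 4, 4); m1[2, 3] <- TRUE
  expect_equal(roi_mean_spectrum(cube, m1), cube$transmittance[2, 3, ])
  expect_error(roi_mean_spectrum(cube, matrix(FALSE, 4, 4)), "empty")

  const <- cube; const$transmittance[] <- 0.7
  mall <- matrix(TRUE, 4, 4)
  expect_equal(roi_mean_spectrum(const, mall), rep(0.7, 6))

  m2 <- matrix(FALSE, 4, 4); m2[c(1, 9)] <- TRUE
  expect_equal(roi_mean_spectrum(cube, m2),
               (cube$transmittance[1, 1, ] + cube$transmittance[1, 3, ]) / 2)

  # permutation invariance in pixel order
  perm <- sample(16)
  tr2 <- apply(cube$transmittance, 3, function(sl) as.vector(sl)[perm])
  cube2 <- structure(list(transmittance = array(tr2, c(4, 4, 6)),
                          wavelengths_nm = 1:6), class = "hsi_cube")
  mask2 <- matrix(as.vector(mall)[perm], 4, 4)
  expect_equal(roi_mean_spectrum(cube2, mask2), roi_mean_spectrum(cube, mall))
})

test_that("spectrum sets round-trip through CSV", {
  ss <- planted_band_dataset(n_per_class = 3, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_set(ss, path)
  back <- read_spectrum_set(path)
  expect_equal(back$spectra, ss$spectra, ignore_attr = TRUE, tolerance = 1e-10)
  expect_identical(back$labels, ss$labels)
  expect_identical(back$sample_ids, ss$sample_ids)
  expect_equal(back$wavelengths_nm, ss$wavelengths_nm, tolerance = 1e-6)
})

test_that("ENVI cubes and masks round-trip through disk", {
  cfg <- flat_scene()
  ds <- generate_dataset(cfg, 1, seed = 2, bands = 1:6)
  dir <- withr::local_tempdir()
  man <- export_dataset(ds, dir, data_type = 5)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  for (interleave in c("bsq", "bil", "bip")) {
    pre <- file.path(dir, paste0("cube_", interleave))
    write_envi(ds$samples[[2]]$raw, pre, ds$samples[[2]]$wavelengths_nm,
               interleave = interleave, data_type = 5)
    back <- read_envi(pre)
    expect_equal(back$cube, ds$samples[[2]]$raw, tolerance = 0)
    expect_equal(back$wavelengths_nm, ds$samples[[2]]$wavelengths_nm,
                 tolerance = 1e-6)
  }
  # float32 loses precision but stays close
  pre32 <- file.path(dir, "cube32")
  write_envi(ds$samples[[1]]$raw, pre32, data_type = 4)
  expect_equal(read_envi(pre32)$cube, ds$samples[[1]]$raw, tolerance = 1e-6)
  m <- ds$samples[[1]]$roi_mask
  expect_identical(read_mask_png(paste0(man$path[1], "_mask.png")), m)
})
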