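test_that("image preparation crops, rescales, normalizes, and replicates channels", {
  set.seed(2)
  img <- matrix(runif(224 * 224), 224, 224)
  prep <- prepare_image(img, 224)
  expect_identical(dim(prep), c(224L, 224L, 3L))
  expect_identical(prep[, , 1], prep[, , 2])
  expect_identical(prep[, , 1], prep[, , 3])
  # square input: crop is the identity, so only min-max scaling is applied
  expect_equal(prep[, , 1], (img - min(img)) / diff(range(img)))
  expect_equal(range(prep), c(0, 1))

  expect_equal(prepare_image(matrix(5, 50, 50), 32),
               array(0, c(32, 32, 3)))
  bad <- img; bad[3, 3] <- NA
  expect_error(prepare_image(bad, 64), "non-finite")
  expect_error(prepare_image(matrix(1, 4, 4), 32), "8x8")
})

test_that("bilinear resizing matches a naive oracle and maps corners to corners", {
  set.seed(8)
  img <- matrix(runif(300 * 200), 300, 200)
  side <- 200
  crop <- img[51:250, ]  # centered 200x200 crop of a 300x200 image
  out <- bilinear_resize(crop, 64, 64)
  expect_equal(out, naive_bilinear(crop, 64, 64), tolerance = 1e-12)
  expect_equal(out[c(1, 64), c(1, 64)], crop[c(1, side), c(1, side)])
  # prepare_image uses the same crop convention
  prep <- prepare_image(img, 64)
  expect_equal(prep[, , 1],
               {
                 r <- naive_bilinear(crop, 64, 64)
                 (r - min(r)) / diff(range(r))
               },
               tolerance = 1e-12)
  # upsampling and downsampling against the oracle
  small <- matrix(runif(9), 3, 3)
  expect_equal(bilinear_resize(small, 7, 5), naive_bilinear(small, 7, 5),
               tolerance = 1e-12)
})

test_that("the seeded convolution stack matches a direct convolution oracle", {
  set.seed(4)
  x <- array(runif(20 * 18 * 3), c(20, 18, 3))
  W <- matrix(rnorm(5 * 5 * 3 * 7), 75, 7)
  expect_equal(mycohsi:::conv_relu(x, W, k = 5L, stride = 3L),
               naive_conv_relu(x, W, k = 5, stride = 3), tolerance = 1e-12)
})

test_that("the seeded backend is deterministic with a fixed 2048-d output", {
  b <- feature_backend("seeded_conv", seed = 9, out_size = 128)
  expect_identical(b$feature_dim, 2048L)
  expect_true(b$deterministic)
  img <- matrix(runif(64 * 64), 64, 64)
  f1 <- backend_features(b, prepare_image(img, 128))
  f2 <- backend_features(b, prepare_image(img, 128))
  expect_identical(f1, f2)
  expect_length(f1, 2048)
  # same seed rebuilds identical weights; different seeds differ
  b2 <- feature_backend("seeded_conv", seed = 9, out_size = 128)
  expect_identical(b$weights, b2$weights)
  b3 <- feature_backend("seeded_conv", seed = 10, out_size = 128)
  expect_false(identical(b$weights, b3$weights))

  expect_error(feature_backend("resnet50_pretrained"), "seeded_conv")
  expect_error(feature_backend(out_size = 64), "2x2")
  expect_error(feature_backend(feature_dim = 1024), "2048")
})

test_that("feature extraction is per-sample with the stated aggregation", {
  b <- feature_backend(seed = 3, out_size = 128)
  set.seed(11)
  imgA <- array(runif(64 * 64 * 2), c(64, 64, 2))
  imgB <- array(runif(64 * 64 * 2), c(64, 64, 2))
  fm <- extract_features(list(imgA, imgA, imgB), b, labels = c(0, 0, 3))
  expect_identical(dim(fm$features), c(3L, 2048L))
  expect_identical(fm$features[1, ], fm$features[2, ])  # identical samples
  expect_false(identical(fm$features[1, ], fm$features[3, ]))

  # permuting samples permutes rows identically (no cross-sample state)
  fm2 <- extract_features(list(imgB, imgA), b)
  expect_identical(fm2$features[1, ], fm$features[3, ])
  expect_identical(fm2$features[2, ], fm$features[1, ])

  # a stack whose band images are all identical: mean equals the single image
  rep3 <- array(rep(imgA[, , 1], 3), c(64, 64, 3))
  fm3 <- extract_features(list(rep3), b, aggregate = "mean")
  single <- backend_features(b, prepare_image(imgA[, , 1], 128))
  expect_equal(fm3$features[1, ], single, tolerance = 1e-12)
  fmx <- extract_features(list(rep3), b, aggregate = "max")
  expect_equal(fmx$features[1, ], single, tolerance = 1e-12)
})

test_that("backend features separate the widest and narrowest phenotypes", {
  cfg <- desk_scene()
  accs <- vapply(1:5, function(rep_seed) {
    man <- dataset_manifest(cfg, 12, 400 + rep_seed)
    man <- man[man$label %in% c(0, 3), ]
    imgs <- dataset_band_images(cfg, man, band_indices = c(30L, 90L))
    b <- feature_backend(seed = rep_seed, out_size = 128)
    fm <- extract_features(imgs, b, labels = man$label)
    Z <- scale(fm$features); Z[!is.finite(Z)] <- 0
    y <- factor(man$label)
    folds <- rep_len(1:4, length(y))
    correct <- 0
    for (f in 1:4) {
      tr <- which(folds != f); te <- which(folds == f)
      m <- kernlab::ksvm(Z[tr, ], y[tr], kernel = "vanilladot",
                         kpar = list(), C = 1, scaled = FALSE)
      correct <- correct +
        sum(as.character(kernlab::predict(m, Z[te, ])) == as.character(y[te]))
    }
    correct / length(y)
  }, numeric(1))
  expect_gte(median(accs), 0.7)
})
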