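test_that("Kennard-Stone selection is max-min with deterministic tie-breaks", {
  X <- matrix(c(0, 1, 10), ncol = 1)
  expect_identical(kennard_stone(X, 2), c(1L, 3L))  # the max-distance pair
  # n_select = n: all points in a deterministic order
  full <- kennard_stone(X, 3)
  expect_identical(sort(full), 1:3)
  expect_identical(full, kennard_stone(X, 3))
  expect_error(kennard_stone(matrix(1, 5, 2), 3), "coincide")
  expect_error(kennard_stone(X, 1), "n_select")
})

test_that("Kennard-Stone equals the stepwise recomputation oracle", {
  for (s in 1:6) {
    set.seed(40 + s)
    X <- matrix(rnorm(36), 12, 3)
    expect_identical(kennard_stone(X, 6), as.integer(ks_oracle(X, 6)))
    expect_identical(kennard_stone(X, 12), as.integer(ks_oracle(X, 12)))
  }
})

test_that("Kennard-Stone is permutation-covariant", {
  set.seed(50)
  X <- matrix(rnorm(30), 10, 3)
  sel <- kennard_stone(X, 5)
  perm <- sample(10)
  sel_p <- kennard_stone(X[perm, ], 5)
  expect_setequal(perm[sel_p], sel)
})

test_that("stratified 4:1 splits are exact, disjoint, and reproducible", {
  ss <- planted_band_dataset(n_per_class = 10, seed = 6)  # 40 samples
  sp <- ks_split(ss, ratio = 0.8)
  expect_length(sp$train_idx, 32)
  expect_length(sp$test_idx, 8)
  for (cl in 0:3) {
    expect_identical(sum(ss$labels[sp$train_idx] == cl), 8L)
    expect_identical(sum(ss$labels[sp$test_idx] == cl), 2L)
  }
  expect_identical(sort(c(sp$train_idx, sp$test_idx)), 1:40)
  expect_identical(sp, ks_split(ss, ratio = 0.8))  # no randomness
  expect_identical(intersect(sp$train_ids, sp$test_ids), character(0))
  glob <- ks_split(ss, ratio = 0.8, stratified = FALSE)
  expect_length(glob$train_idx, 32)
  tiny <- subset_spectra(ss, c(1, 11, 21, 31))
  expect_error(ks_split(tiny, 0.8), "too small")
})

test_that("classification reports implement per-class TP/TN/FP/FN accuracy", {
  expect_equal(evaluate_predictions(c(0, 1, 2, 3), c(0, 1, 2, 3))$accuracy, 1)
  all_one <- evaluate_predictions(rep(2, 24), rep(0:3, each = 6), classes = 0:3)
  expect_equal(all_one$accuracy, 0.25)

  truth <- rep(0:3, each = 6)
  pred <- truth; pred[c(1, 8)] <- c(1, 2)  # 2 errors in 24
  rep2 <- evaluate_predictions(pred, truth)
  expect_equal(rep2$accuracy, 22 / 24)
  expect_identical(sum(rep2$confusion_matrix), 24L)
  pc <- rep2$per_class
  # counts are consistent with the confusion matrix and Eq.-style accuracy
  expect_equal(pc$tp + pc$fn, unname(rowSums(rep2$confusion_matrix)))
  expect_equal(pc$tp + pc$fp, unname(colSums(rep2$confusion_matrix)))
  expect_equal(pc$binary_accuracy, (pc$tp + pc$tn) / 24)
  expect_identical(unique(pc$tp + pc$tn + pc$fp + pc$fn), 24L)
  # micro view: trace / total equals the plain accuracy
  expect_equal(sum(diag(rep2$confusion_matrix)) / 24, rep2$accuracy)
  expect_error(evaluate_predictions(1:3, 1:4), "lengths")
  expect_error(evaluate_predictions(c(0, 9), c(0, 1), classes = 0:3), "class set")
})

test_that("the comparison runner wires every stage together", {
  cfg <- scene_config(image_height = 48, image_width = 48, n_bands = 40,
                      filaments_per_image = c(1, 3))
  res <- run_comparison(cfg, n_per_class = 10, seed = 5,
                        pretreatments = c("none", "snv"),
                        n_min = 1, n_max = 4, spa_starts = c(1, 10, 20, 30),
                        cv_folds = 3,
                        backend = feature_backend(seed = 2, out_size = 128),
                        mu_grid = c(0, 0.5, 1), C_grid = c(1, 10),
                        gamma_s_grid = 0.01, gamma_w_grid = 0.001)
  expect_s3_class(res, "degradation_comparison")
  expect_identical(res$pretreatment_table$pretreatment, c("none", "snv"))
  expect_identical(res$model_table$model,
                   c("spectrum_raw", "spectrum_spa", "image_raw",
                     "image_features", "fused"))
  accs <- c(res$model_table$train_accuracy, res$model_table$test_accuracy,
            res$pretreatment_table$test_accuracy)
  expect_true(all(accs >= 0 & accs <= 1))
  expect_true(all(res$selection$selected_wavelengths_nm >= 400 &
                    res$selection$selected_wavelengths_nm <= 1000))
  expect_identical(res$fused$test$n, length(res$split$test_idx))
  expect_true(res$fused$config$mu >= 0 && res$fused$config$mu <= 1)
  # the split is shared: train + test cover all 40 samples
  expect_identical(sort(c(res$split$train_idx, res$split$test_idx)), 1:40)
})
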