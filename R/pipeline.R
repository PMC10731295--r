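# End-to-end orchestration: two-pass dataset realization (full cubes are
# never all held in memory; samples are regenerated from their manifest
# seeds when the selected-band images are needed) and the model-comparison
# runner.

#' Realize a synthetic dataset as ROI spectra (pass 1)
#'
#' Generates each sample in turn, calibrates it, takes the ROI mean
#' spectrum, and also keeps a small flattened thumbnail of the band-mean
#' transmittance image (the "raw pixel" image features). Full cubes are
#' discarded sample by sample.
#'
#' @param config a [scene_config()].
#' @param n_per_class samples per class.
#' @param seed master seed (per-sample seeds derive from it).
#' @param window analysis wavelength window passed to [crop_bands()].
#' @param thumbnail_px side of the flattened band-mean thumbnail.
#' @return an `hsi_spectra_dataset`: `spectra` (cropped [spectrum_set()]),
#'   `manifest`, `band_map` (full-axis indices of the cropped columns),
#'   `raw_image_features` (n x thumbnail_px^2), `config`, `window`.
#' @export
dataset_spectra <- function(config, n_per_class, seed,
                            window = c(400, 1000), thumbnail_px = 32) {
  manifest <- dataset_manifest(config, n_per_class, seed)
  n <- nrow(manifest)
  specs <- matrix(NA_real_, n, config$n_bands)
  thumbs <- matrix(NA_real_, n, thumbnail_px^2)
  for (i in seq_len(n)) {
    s <- generate_sample(config, manifest$label[i], manifest$seed[i])
    cube <- calibrate(s)
    specs[i, ] <- roi_mean_spectrum(cube, s$roi_mask)
    d <- dim(cube$transmittance)
    band_mean <- matrix(rowMeans(matrix(cube$transmittance, d[1] * d[2], d[3])),
                        d[1], d[2])
    thumbs[i, ] <- as.vector(bilinear_resize(band_mean, thumbnail_px, thumbnail_px))
    rm(s, cube)
  }
  full <- spectrum_set(specs, config$wavelengths_nm, manifest$label, manifest$id)
  cropped <- crop_bands(full, window[1], window[2])
  structure(list(spectra = cropped,
                 manifest = manifest,
                 band_map = attr(cropped, "kept_bands"),
                 raw_image_features = thumbs,
                 config = config, window = window),
            class = "hsi_spectra_dataset")
}

#' Regenerate calibrated band images at selected wavelengths (pass 2)
#'
#' Samples are rebuilt from their manifest seeds restricted to the requested
#' full-axis band indices (the generator reproduces exactly the slices of
#' the full cube), then calibrated.
#'
#' @param config the [scene_config()] the manifest was built under.
#' @param manifest manifest data.frame (`id`, `label`, `seed`).
#' @param band_indices full-axis band indices (e.g.
#'   `band_map[sel$selected_indices]`).
#' @return list with one H x W x length(band_indices) transmittance array
#'   per sample.
#' @export
dataset_band_images <- function(config, manifest, band_indices) {
  lapply(seq_len(nrow(manifest)), function(i) {
    s <- generate_sample(config, manifest$label[i], manifest$seed[i],
                         bands = band_indices)
    calibrate(s)$transmittance
  })
}

eval_single_modality <- function(X_train, X_test, y_train, y_test,
                                 C_grid, gamma_grid, cv_folds, seed) {
  gs <- grid_search_single(X_train, y_train, C_grid = C_grid,
                           gamma_grid = gamma_grid, cv_folds = cv_folds,
                           seed = seed)
  model <- train_fused_model(X_train, X_train, y_train, gs$best)
  pr_tr <- predict(model, X_train, X_train)
  pr_te <- predict(model, X_test, X_test)
  list(config = gs$best, cv_accuracy = gs$best_accuracy,
       train = evaluate_predictions(pr_tr, y_train),
       test = evaluate_predictions(pr_te, y_test),
       model = model)
}

#' Run the full pretreatment- and model-comparison experiment
#'
#' Reproduces the experimental grid on synthetic data: (i) a pretreatment
#' comparison (none/SG/MSC/SNV spectra into an RBF-SVM) and (ii) a model
#' comparison (raw spectra, SPA-selected pretreated spectra, raw band-image
#' pixels, backend image features, and the fused spectral+image kernel).
#' The dataset is split 4:1 by stratified Kennard-Stone once; every model
#' row shares the split. Model selection (grids, SPA, MSC reference) uses
#' the training partition only.
#'
#' @param config a [scene_config()].
#' @param n_per_class samples per class (the study analogue is 150; the desk
#'   default is 30).
#' @param seed master seed for generation, folds, and the backend.
#' @param window analysis wavelength window.
#' @param pretreat pretreatment feeding the SPA/fusion pathway.
#' @param pretreatments rows of the pretreatment table (`NULL` skips it).
#' @param n_min,n_max,spa_starts SPA sizing; see [select_bands()].
#' @param cv_folds folds for SPA sizing and SVM grids.
#' @param backend a [feature_backend()] (`NULL`: seeded backend derived from
#'   `seed`).
#' @param aggregate band-image feature aggregation, `"mean"` or `"max"`.
#' @param mu_grid,C_grid,gamma_s_grid,gamma_w_grid SVM model-selection
#'   grids (see [grid_search_fused()]; `"scale"` pins a gamma to the scale
#'   heuristic).
#' @param fused_gamma_s_grid,fused_gamma_w_grid gamma grids for the fused
#'   model only; `NULL` inherits `gamma_s_grid` / `gamma_w_grid`.
#' @param thumbnail_px side of the raw-pixel thumbnail features.
#' @param verbose print stage progress.
#' @return a `degradation_comparison`: `pretreatment_table`, `model_table`,
#'   `selection`, `split`, `fused` (config + report), `dataset` manifest.
#' @export
run_comparison <- function(config = scene_config(), n_per_class = 30, seed = 1,
                           window = c(400, 1000),
                           pretreat = "snv",
                           pretreatments = c("none", "sg", "msc", "snv"),
                           n_min = 1, n_max = 16, spa_starts = NULL,
                           cv_folds = 5,
                           backend = NULL, aggregate = "mean",
                           mu_grid = seq(0, 1, 0.1),
                           C_grid = c(0.1, 1, 10, 100),
                           gamma_s_grid = NULL, gamma_w_grid = NULL,
                           fused_gamma_s_grid = NULL, fused_gamma_w_grid = NULL,
                           thumbnail_px = 32, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  seeds <- derive_seeds(seed, 4)

  say("pass 1: generating %d samples and extracting ROI spectra",
      n_per_class * length(config$classes))
  ds <- dataset_spectra(config, n_per_class, seed, window, thumbnail_px)
  ss <- ds$spectra
  split <- ks_split(ss, ratio = 0.8, stratified = TRUE, space = "snv")
  tri <- split$train_idx; tei <- split$test_idx
  y_tr <- ss$labels[tri]; y_te <- ss$labels[tei]
  tr_raw <- subset_spectra(ss, tri)
  te_raw <- subset_spectra(ss, tei)

  pre_tab <- NULL
  if (!is.null(pretreatments)) {
    say("pretreatment comparison: %s", paste(pretreatments, collapse = ", "))
    rows <- lapply(pretreatments, function(m) {
      ptr <- preprocess_spectra(tr_raw, m)
      pte <- preprocess_spectra(te_raw, m,
                                msc_reference = attr(ptr, "msc_reference"))
      r <- eval_single_modality(ptr$spectra, pte$spectra, y_tr, y_te,
                                C_grid, gamma_s_grid, cv_folds, seeds[1])
      data.frame(pretreatment = m,
                 train_accuracy = r$train$accuracy,
                 test_accuracy = r$test$accuracy)
    })
    pre_tab <- do.call(rbind, rows)
  }

  say("SPA band selection on %s-pretreated training spectra", pretreat)
  tr_p <- preprocess_spectra(tr_raw, pretreat)
  te_p <- preprocess_spectra(te_raw, pretreat,
                             msc_reference = attr(tr_p, "msc_reference"))
  sel <- select_bands(tr_p, n_min = n_min, n_max = n_max,
                      cv_folds = cv_folds, seed = seeds[2], starts = spa_starts)
  spa_tr <- apply_selection(tr_p, sel)$spectra
  spa_te <- apply_selection(te_p, sel)$spectra

  say("pass 2: band images at %d selected wavelengths + backend features",
      sel$n_bands)
  backend <- backend %||% feature_backend("seeded_conv", seed = seeds[3])
  full_bands <- ds$band_map[sel$selected_indices]
  imgs <- dataset_band_images(config, ds$manifest, full_bands)
  fm <- extract_features(imgs, backend, aggregate = aggregate,
                         labels = ss$labels, sample_ids = ss$sample_ids)
  img_tr <- fm$features[tri, , drop = FALSE]
  img_te <- fm$features[tei, , drop = FALSE]
  pix_tr <- ds$raw_image_features[tri, , drop = FALSE]
  pix_te <- ds$raw_image_features[tei, , drop = FALSE]

  say("model comparison")
  res <- list(
    spectrum_raw = eval_single_modality(tr_raw$spectra, te_raw$spectra,
                                        y_tr, y_te, C_grid, gamma_s_grid,
                                        cv_folds, seeds[1]),
    spectrum_spa = eval_single_modality(spa_tr, spa_te, y_tr, y_te,
                                        C_grid, gamma_s_grid, cv_folds, seeds[1]),
    image_raw = eval_single_modality(pix_tr, pix_te, y_tr, y_te,
                                     C_grid, gamma_w_grid, cv_folds, seeds[1]),
    image_features = eval_single_modality(img_tr, img_te, y_tr, y_te,
                                          C_grid, gamma_w_grid, cv_folds, seeds[1]))

  gs <- grid_search_fused(spa_tr, img_tr, y_tr,
                          mu_grid = mu_grid, C_grid = C_grid,
                          gamma_s_grid = fused_gamma_s_grid %||% gamma_s_grid,
                          gamma_w_grid = fused_gamma_w_grid %||% gamma_w_grid,
                          cv_folds = cv_folds, seed = seeds[1])
  fused_model <- train_fused_model(spa_tr, img_tr, y_tr, gs$best)
  fused <- list(config = gs$best, cv_accuracy = gs$best_accuracy,
                train = evaluate_predictions(predict(fused_model, spa_tr, img_tr), y_tr),
                test = evaluate_predictions(predict(fused_model, spa_te, img_te), y_te),
                model = fused_model)
  res$fused <- fused

  model_tab <- do.call(rbind, lapply(names(res), function(nm) {
    data.frame(model = nm,
               train_accuracy = res[[nm]]$train$accuracy,
               test_accuracy = res[[nm]]$test$accuracy)
  }))

  structure(list(pretreatment_table = pre_tab,
                 model_table = model_tab,
                 results = res,
                 selection = sel,
                 split = split,
                 fused = fused,
                 manifest = ds$manifest,
                 seed = seed),
            class = "degradation_comparison")
}

#' @export
print.degradation_comparison <- function(x, ...) {
  cat("<degradation_comparison>\n")
  if (!is.null(x$pretreatment_table)) {
    cat("\nPretreatment comparison (spectral RBF-SVM):\n")
    print(format_accuracy_table(x$pretreatment_table))
  }
  cat("\nModel comparison:\n")
  print(format_accuracy_table(x$model_table))
  cat(sprintf("\nSPA: %d bands, CV RMSE %.4f; fused mu = %.2f\n",
              x$selection$n_bands, x$selection$chosen_rmse,
              x$fused$config$mu))
  invisible(x)
}

format_accuracy_table <- function(tab) {
  out <- tab
  for (cl in c("train_accuracy", "test_accuracy")) {
    out[[cl]] <- sprintf("%.1f%%", 100 * tab[[cl]])
  }
  out
}
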