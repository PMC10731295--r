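#!/usr/bin/env Rscript

# Final model comparison: raw spectra, SPA-selected SNV spectra, raw pixel
# thumbnails, backend image features, and the fused spectral+image kernel
# SVM with grid-searched fusion weight mu. All selection on the training
# partition; the test partition is touched once per model.

suppressMessages(library(mycohsi))

out <- "results"
ss <- read_spectrum_set(file.path(out, "roi_spectra.csv"))
sel <- read_band_selection(file.path(out, "band_selection.json"))
thumbs <- as.matrix(read.csv(file.path(out, "band_mean_thumbnails.csv"))[, -1])
feats <- read.csv(file.path(out, "image_features.csv"))
stopifnot(identical(feats$id, ss$sample_ids))
F <- as.matrix(feats[, -(1:2)])

split <- ks_split(ss, ratio = 0.8, stratified = TRUE, space = "snv")
tri <- split$train_idx; tei <- split$test_idx
y_tr <- ss$labels[tri]; y_te <- ss$labels[tei]

tr_raw <- subset_spectra(ss, tri); te_raw <- subset_spectra(ss, tei)
tr_snv <- preprocess_spectra(tr_raw, "snv"); te_snv <- preprocess_spectra(te_raw, "snv")
spa_tr <- apply_selection(tr_snv, sel$selected_indices)$spectra
spa_te <- apply_selection(te_snv, sel$selected_indices)$spectra

single <- function(Xtr, Xte) {
  gs <- grid_search_single(Xtr, y_tr, cv_folds = 5, seed = 42)
  m <- train_fused_model(Xtr, Xtr, y_tr, gs$best)
  c(train = mean(predict(m, Xtr, Xtr) == y_tr),
    test = mean(predict(m, Xte, Xte) == y_te))
}

rows <- rbind(
  spectrum_raw = single(tr_raw$spectra, te_raw$spectra),
  spectrum_spa = single(spa_tr, spa_te),
  image_raw = single(thumbs[tri, ], thumbs[tei, ]),
  image_features = single(F[tri, ], F[tei, ]))

gs <- grid_search_fused(spa_tr, F[tri, ], y_tr, mu_grid = seq(0, 1, 0.1),
                        gamma_s_grid = "scale", gamma_w_grid = "scale",
                        cv_folds = 5, seed = 42)
fused <- train_fused_model(spa_tr, F[tri, ], y_tr, gs$best)
pred_te <- predict(fused, spa_te, F[tei, ])
rows <- rbind(rows, fused = c(train = mean(predict(fused, spa_tr, F[tri, ]) == y_tr),
                              test = mean(pred_te == y_te)))

tab <- data.frame(model = rownames(rows), rows, row.names = NULL)
write.csv(tab, file.path(out, "model_comparison.csv"), row.names = FALSE)
message("model comparison (train / test accuracy):")
print(transform(tab, train = sprintf("%.1f%%", 100 * train),
                test = sprintf("%.1f%%", 100 * test)))
message(sprintf("fused weight mu = %.2f (mu = 1 is spectral-only)", gs$best$mu))

report <- evaluate_predictions(pred_te, y_te, classes = sort(unique(ss$labels)))
print(report)
write.csv(as.data.frame(report$confusion_matrix),
          file.path(out, "fused_test_confusion.csv"), row.names = FALSE)
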