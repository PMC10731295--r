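#!/usr/bin/env Rscript

# Compare spectral pretreatments (none / SG / MSC / SNV) feeding an RBF-SVM
# on the ROI spectra written by 01_simulate_dataset.R, under the stratified
# Kennard-Stone 4:1 split. MSC's reference is fit on the training partition
# only.

suppressMessages(library(mycohsi))

out <- "results"
ss <- read_spectrum_set(file.path(out, "roi_spectra.csv"))
split <- ks_split(ss, ratio = 0.8, stratified = TRUE, space = "snv")
tr <- subset_spectra(ss, split$train_idx)
te <- subset_spectra(ss, split$test_idx)

rows <- lapply(c("none", "sg", "msc", "snv"), function(m) {
  ptr <- preprocess_spectra(tr, m)
  pte <- preprocess_spectra(te, m, msc_reference = attr(ptr, "msc_reference"))
  gs <- grid_search_single(ptr$spectra, tr$labels, cv_folds = 5, seed = 42)
  model <- train_fused_model(ptr$spectra, ptr$spectra, tr$labels, gs$best)
  data.frame(pretreatment = m,
             cv_accuracy = gs$best_accuracy,
             train_accuracy = mean(predict(model, ptr$spectra, ptr$spectra) == tr$labels),
             test_accuracy = mean(predict(model, pte$spectra, pte$spectra) == te$labels))
})
tab <- do.call(rbind, rows)
write.csv(tab, file.path(out, "pretreatment_comparison.csv"), row.names = FALSE)
message("pretreatment comparison (train / test accuracy):")
print(transform(tab,
                train_accuracy = sprintf("%.1f%%", 100 * train_accuracy),
                test_accuracy = sprintf("%.1f%%", 100 * test_accuracy)))
message("scatter-correcting pretreatments (MSC/SNV) should beat raw spectra.")
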