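#!/usr/bin/env Rscript

# SPA band selection on the SNV-pretreated training spectra: sweep every
# start band, size the subset by cross-validated RMSE of a linear model of
# the degradation grade, and persist the selection and the RMSE curve.

suppressMessages(library(mycohsi))

out <- "results"
ss <- read_spectrum_set(file.path(out, "roi_spectra.csv"))
split <- ks_split(ss, ratio = 0.8, stratified = TRUE, space = "snv")
tr <- preprocess_spectra(subset_spectra(ss, split$train_idx), "snv")

sel <- select_bands(tr, n_min = 1, n_max = 20, cv_folds = 5, seed = 42)
print(sel)
write_band_selection(sel, file.path(out, "band_selection.json"))
write.csv(sel$rmse_curve, file.path(out, "spa_rmse_curve.csv"), row.names = FALSE)
message(sprintf("RMSE falls from %.3f (1 band) to %.3f at N = %d",
                sel$rmse_curve$rmse[1], sel$chosen_rmse, sel$n_bands))
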