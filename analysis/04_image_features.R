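#!/usr/bin/env Rscript

# Extract per-sample image features at the SPA-selected wavelengths: cubes
# are regenerated from the manifest seeds restricted to those bands,
# calibrated, and pushed through the seeded convolutional backend (2048-d,
# mean-aggregated across band images).

suppressMessages(library(mycohsi))

out <- "results"
manifest <- read.csv(file.path(out, "manifest.csv"))
sel <- read_band_selection(file.path(out, "band_selection.json"))
ss <- read_spectrum_set(file.path(out, "roi_spectra.csv"))

cfg <- scene_config()
full_axis <- cfg$wavelengths_nm
# map selected (cropped-axis) wavelengths back to full-axis band indices
bands <- vapply(sel$selected_wavelengths_nm,
                function(wl) which.min(abs(full_axis - wl)), integer(1))

message(sprintf("Regenerating %d samples at %d selected bands", nrow(manifest),
                length(bands)))
imgs <- dataset_band_images(cfg, manifest, bands)
backend <- feature_backend("seeded_conv", seed = 42)
fm <- extract_features(imgs, backend, aggregate = "mean",
                       labels = ss$labels, sample_ids = ss$sample_ids)
write.csv(data.frame(id = fm$sample_ids, label = fm$labels, fm$features),
          file.path(out, "image_features.csv"), row.names = FALSE)
message(sprintf("wrote %d x %d feature matrix (backend: %s)",
                nrow(fm$features), ncol(fm$features), fm$backend_name))
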