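#!/usr/bin/env Rscript

# Simulate the micro-hyperspectral study analogue and persist its compact
# products: the sample manifest, the cropped ROI spectrum table, the
# raw-pixel thumbnails, and one exemplar cube per class as ENVI files.
# Full cubes are regenerated from manifest seeds by later steps, so this is
# the only step that has to touch every cube end to end.

suppressMessages(library(mycohsi))

seed <- 20260928L
n_per_class <- 30L
out <- "results"
dir.create(out, showWarnings = FALSE)

cfg <- scene_config()  # 128 x 128 px, 360 bands over 401-1046 nm
message(sprintf("Generating %d samples per class at %dx%d px, %d bands",
                n_per_class, cfg$image_height, cfg$image_width, cfg$n_bands))

ds <- dataset_spectra(cfg, n_per_class, seed)
write.csv(ds$manifest, file.path(out, "manifest.csv"), row.names = FALSE)
write_spectrum_set(ds$spectra, file.path(out, "roi_spectra.csv"))
write.csv(data.frame(id = ds$manifest$id, ds$raw_image_features),
          file.path(out, "band_mean_thumbnails.csv"), row.names = FALSE)

# exemplar cubes (one per class, a few bands) as ENVI, for inspection
envi_dir <- file.path(out, "envi_examples")
exemplars <- ds$manifest[!duplicated(ds$manifest$label), ]
small <- generate_dataset(cfg, 1, seed, bands = seq(1, 360, by = 60))
invisible(export_dataset(small, envi_dir, data_type = 4))

# class-mean ROI spectra: degraded classes sit above the undegraded strain
ss <- ds$spectra
class_means <- t(vapply(sort(unique(ss$labels)), function(l) {
  colMeans(ss$spectra[ss$labels == l, , drop = FALSE])
}, numeric(ncol(ss$spectra))))
write.csv(data.frame(label = sort(unique(ss$labels)), class_means),
          file.path(out, "class_mean_spectra.csv"), row.names = FALSE)

lev <- tapply(rowMeans(ss$spectra), ss$labels, mean)
message(paste("mean ROI transmittance by class (increases with degradation in",
              "expectation; per-dataset means also carry scatter noise):"))
print(round(lev, 4))
message(sprintf("wrote manifest (%d rows), spectra (%d bands kept), thumbnails",
                nrow(ds$manifest), ncol(ss$spectra)))
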