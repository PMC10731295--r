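Package: mycohsi
Title: Micro-Hyperspectral Grading of Edible-Fungus Strain Degradation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for grading subculture degradation of Pleurotus
    geesteranus strains from micro-hyperspectral transmittance cubes of
    growing mycelium. Provides a seeded synthetic scene generator that
    emulates the imaging setup (filamentous mycelium, smooth endmember
    transmittance curves, white/dark reference frames, scatter and baseline
    distortions), black-and-white calibration, region-of-interest mean
    spectra, SNV/MSC/Savitzky-Golay spectral pretreatment, successive
    projections algorithm (SPA) band selection with cross-validated RMSE
    model sizing, seeded convolutional image features at the selected
    wavelengths, a fused-kernel (weighted spectral + image RBF) support
    vector machine with grid-searched fusion weight, and Kennard-Stone 4:1
    partitioning with accuracy and confusion-matrix reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    kernlab,
    jsonlite,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
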