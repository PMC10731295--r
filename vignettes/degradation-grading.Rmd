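---
title: "Grading mushroom strain degradation from micro-hyperspectral cubes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading mushroom strain degradation from micro-hyperspectral cubes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Edible-fungus strains lose vigor as they are subcultured: growth slows,
extracellular enzyme activity drops, and using a degraded spawn batch is
costly. *Pleurotus geesteranus* degradation shows up early in the growing
mycelium itself — degraded strains grow narrower hyphae and transmit
slightly more light — which makes transmittance micro-hyperspectral imaging
a candidate for early, non-destructive grading. `mycohsi` implements that
grading pipeline end to end: cube calibration, ROI spectra, spectral
pretreatment, band selection, image features at the selected bands, and a
fused spectral+image kernel SVM, graded into four ordinal classes (0 =
undegraded through 3 = heavily degraded).

Because no public cubes exist for this assay, the package ships a seeded
synthetic scene generator as first-class, tested code. Every experiment in
`analysis/` and every acceptance check runs against it.

## The synthetic scene model

A scene is a stack of H x W band images over an evenly spaced wavelength
axis (default 360 bands, 401-1046 nm). Its construction, in order:

1. **Filament geometry.** Each of 3-6 filaments is a persistent-direction
   random walk entering from a frame edge, rasterized with a Gaussian
   cross-profile whose full width at half maximum is the class width
   parameter. Filament coverage composes as `1 - prod(1 - c_i)`, and the
   ROI mask is the coverage >= 0.5 core (at least 50 pixels; geometry is
   redrawn deterministically if a draw leaves fewer).
2. **Endmember blend.** Per-pixel transmittance is
   `cov * mycelium + (1 - cov) * background`. The background (uninoculated
   agar) is near-transparent and spectrally almost flat; the mycelium curve
   carries the shared peak/valley structure: a pigment absorption band near
   470 nm, a weak dip near 670 nm, and an NIR water band near 960 nm.
3. **Degradation encoding.** The class width means strictly decrease
   (9, 7.5, 6, 4.5 px) and the transmittance offsets strictly increase
   (0, 0.06, 0.12, 0.18) with the degradation label. The offset shifts the
   mycelium curve toward the bright ceiling *and* fades the pigment band
   faster than proportionally while slightly deepening the relative water
   band. The last part matters: a purely uniform brightening is an affine
   change that SNV removes exactly, so a generator built that way would
   make the SNV-pretreated spectra vacuously class-free. Degraded, thinner,
   less pigmented hyphae changing their *relative* band depths is both the
   more plausible physiology and the only encoding on which the
   SNV-then-classify pipeline can work.
4. **Distortions and references.** Each sample draws a multiplicative
   scatter slope (sd 0.05 around 1) and an additive baseline offset
   (sd 0.02) applied to the whole transmittance field — exactly the
   single-reference affine model MSC inverts and SNV normalizes away. The
   white frame is a smooth vignette times a lamp spectrum at 3000 counts;
   the dark frame is flat at 100 counts. Raw counts are
   `dark + (T + noise) * (white - dark)` with i.i.d. Gaussian noise
   (sd 0.005 transmittance units).

All randomness flows from the supplied seed through derived sub-seeds
(geometry, distortion, one per band), so a cube restricted to any band
subset reproduces exactly the corresponding slices of the full cube. That
is what lets the pipeline run in two passes — ROI spectra first, band
images at the selected wavelengths later — without ever holding 120 full
cubes (5.6 GB) in memory.

What the generator does **not** emulate: optics (no point-spread function,
no defocus), hyphal branching morphology, spatially varying medium
chemistry, or the wavelength-dependent detector noise floor of a real
spectrograph. Passing tests therefore demonstrate that the pipeline's
statistics behave as designed under the stated model, not that the
accuracies transfer to real dishes.

## Calibration and ROI spectra

Black/white correction is `R = (I_raw - I_dark) / (I_ref - I_dark)` with
per-pixel, per-band reference frames (the white reference is an image of
uninoculated medium, not a reflectance tile). Denominators smaller than
`epsilon` are flagged and zeroed; more than 1% of them is an error. The
output is floored at 0 and clipped at 2 by default, since noise can push
counts above the white reference.

Band cropping keeps wavelengths inside an inclusive `[low, high]` window.
On the uniform synthetic axis the default 400-1000 nm window keeps 334 of
the 360 bands; a real spectrograph axis, which is never perfectly uniform,
can keep a slightly different count over the same nominal window. The ROI
spectrum is the plain arithmetic per-band mean over the masked pixels, one
image, one ROI, one spectrum.

## Spectral pretreatment

Three standard pretreatments, selectable per run:

* **SNV** — per-spectrum `(x - mean) / sd` with the sample (n-1) sd
  (convention fixed and tested). Removes per-sample affine scatter exactly.
* **MSC** — ordinary least squares of each spectrum on a reference
  (training-set mean by default), then `(x - a) / b`. The reference is fit
  on the training partition and reused for held-out spectra to avoid
  leakage.
* **SG smoothing** — Savitzky-Golay local polynomial fit (default window
  11, degree 2 at the ~1.8 nm sampling step). Edge points take the fitted
  values of the nearest full window's polynomial (the usual "interp" mode),
  so a global polynomial of the filter degree is reproduced exactly.

SNV is the default feeding the band-selection and fusion pathway; the
pretreatment is a configuration choice everywhere.

## SPA band selection and RMSE sizing

The successive projections algorithm grows a chain from a start band: at
each step every unselected column is replaced by its projection onto the
orthogonal complement of the most recently selected projected column, and
the column of maximal norm joins the chain. Chained projections make the
selected set mutually orthogonal-in-sequence, which is the point — the
selected bands feed a multiple linear regression with minimal collinearity.

The paper-level procedure leaves two things open, resolved as follows and
fixed by tests: the regression scoring a candidate subset is a multiple
linear regression of the numeric class label on the selected bands under
seeded stratified k-fold cross-validation (the simplest model consistent
with SPA's purpose), and the start band is swept exhaustively (configurable
subsampling for speed), keeping the minimum-RMSE start per subset size.
Ties break to the smallest subset size, then the smallest start index, so
runs are bit-reproducible. Collinear exhaustion is an error reporting the
achievable chain length; rank-deficient folds mark a candidate infeasible
rather than aborting the sweep.

## Image features at the selected wavelengths

Each sample's calibrated band images at the selected wavelengths are
center-cropped to the largest square, bilinearly resized (align-corners
convention: crop corners map to output corners), min-max normalized per
image (a constant image maps to zeros), replicated to three channels, and
pushed through a feature backend to a 2048-dimensional vector; per-band
vectors are mean-aggregated (configurable max) into one vector per sample,
keeping the stated dimensionality.

The default backend, `seeded_conv`, is a fixed three-layer randomly
initialized convolutional stack (He-scaled weights from a seed; kernels
7/5/3, strides 4/3/2, 32/96/512 channels) pooled globally with four
per-channel statistics (mean, max, sd, rms) to 512 x 4 = 2048 features.
Design rationale: random convolutional features are an accepted texture
descriptor and need no downloaded weights, so tests run anywhere and are
bit-deterministic given the seed; *global* pooling statistics make the
descriptor invariant to where filaments happen to lie in the frame, so it
measures width and edge texture rather than layout. A
`resnet50_pretrained` backend name is reserved for the transfer-learning
pathway and errors with instructions to fall back to the seeded backend
when its weights are not installed; nothing in the package trains or
fine-tunes a network.

## The fused-kernel SVM

Spectral and image feature blocks are z-scored (training-fit scalers),
turned into RBF Gram matrices `exp(-gamma ||a - b||^2)`, and fused convexly
as `mu * K_spectral + (1 - mu) * K_image`. One naming caution: in the
source formulation the weighting factor is written against the *spatial*
kernel; this package consistently attaches `mu` to the **spectral** kernel,
so `mu = 1` is the spectral-only model and `mu = 0` the image-only model,
bit-for-bit (tested). A convex combination of PSD matrices is PSD, which
the tests verify numerically alongside the dual feasibility of every fit
(`0 <= alpha_i <= C`, `sum alpha_i y_i = 0` per one-vs-one binary
subproblem).

The SVM itself is a standard precomputed-kernel C-SVC (kernlab) with
one-vs-one multiclass voting. Model selection is a stratified k-fold grid
search over `mu` (0 to 1 by 0.1), `C` (0.1, 1, 10, 100) and per-modality
gammas (scale heuristic `1/(d * var)`, 0.01, 0.1, 1); ties break to the
smaller `C`, then the larger `mu`, then the smaller gammas. Gram matrices
are checked symmetric PSD before fitting; small negative eigenvalues can be
clipped on request (the cross-validation loop does so, since fold
subsetting of a PSD matrix is PSD only up to round-off).

## Partitioning and evaluation

The train/test split is Kennard-Stone at 4:1, run per class (stratified) in
SNV space by default: the max-min selected, most representative points go
to the training set, deterministically, with all ties broken to the lowest
index. Global (unstratified) selection is available. Accuracy is
correct/total; per-class TP/TN/FP/FN come from the one-vs-rest collapse of
the confusion matrix, so the binary accuracy formula is reproduced per
class. Model selection — grids, SPA sizing, the MSC reference — sees the
training partition only.

## Problem sizes and numerical choices

The desk-scale study analogue is 4 classes x 30 cubes of 128 x 128 px and
360 bands, split 96:24; `scripts/acceptance.R` runs it end to end in
about fifteen minutes on one core. Multi-seed experiments in the test suite
(fusion dominance, pretreatment benefit, planted-band recovery) run a
reduced analogue — 64 x 64 px, 120 bands, 12 samples per class, subsampled
SPA starts, scale-heuristic gammas — chosen so ten seeded replicates stay
cheap while every stage still runs end to end; the reduction is a package
choice about replicate cost, and the full scale remains the default
configuration.

Numerical conventions fixed by tests: SNV uses the sample sd and rejects
near-constant spectra (sd below 1e-12); MSC rejects slopes below 1e-8; SPA
treats residual norms below 1e-12 as collinear exhaustion; all tie-breaks
are to the lowest index; calibration clips to [0, 2]; the generator's
zero-noise round trip through calibration is exact to 1e-10 per
pixel-band.

## Known limitations

* The synthetic generator is the only data source; its class-contrast
  magnitudes (width steps, offset steps) are generator parameters, not
  claims about the organism.
* Random-feature backends describe texture well but are not pretrained
  representations; absolute image-pathway accuracies are expected to be
  lower than a transfer-learned backbone would give.
* The RMSE sizing regresses an ordinal grade with a linear model, which is
  convention, not a calibrated model of degradation.
* One image yields one ROI and one spectrum; multi-ROI dishes and
  between-dish effects are out of scope.
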