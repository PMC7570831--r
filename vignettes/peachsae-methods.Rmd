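---
title: "Deep-feature SSC estimation from hyperspectral fruit imagery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep-feature SSC estimation from hyperspectral fruit imagery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peachsae)
```

## The problem

Soluble solids content (SSC, degrees Brix) is a standard index of fruit
internal quality, conventionally measured destructively by refractometry.
Near-infrared hyperspectral imaging offers a non-destructive alternative: a
pushbroom camera records a `rows x cols x bands` reflectance cube per fruit,
and SSC is estimated by regression on features derived from that cube.
`peachsae` implements such a pipeline end to end — calibration, feature
construction, deep-feature extraction with stacked autoencoders (SAE),
random-forest (RF) regression, and pixel-wise SSC mapping — together with a
synthetic phantom generator that provides ground-truth data with the
statistical structure the method assumes, so every stage is testable without
instrument data.

## Reflectance calibration

Raw pushbroom intensities are converted to reflectance with the standard
white/dark correction

$$R = \frac{I_{raw} - I_{dark}}{I_{white} - I_{dark}},$$

applied voxel-wise (`calibrate()`). References may be full frames or
per-band vectors (broadcast); the formula is invariant to any common affine
rescaling of the three intensities, which the test suite checks directly.
Clamping to $[0, 1]$ is on by default because downstream min-max
normalization assumes bounded reflectance; with clamping off, a voxel where
white equals dark raises a degenerate-reference error rather than producing
silent infinities.

## Feature construction

Three payloads are built from each calibrated ROI cube (`sample_features()`):

* **Spectral (453 dims).** The per-band mean over ROI pixels, after dropping
  the first 21 and last 34 of 508 bands. The wavelength grid is uniform over
  908.1–1735.6 nm; the retained bands span roughly 942–1680 nm. Trimming is
  *index-based*, not threshold-based, so the 453 count is exact however the
  grid is rounded; under the uniform grid the last retained band center sits
  at 1680.1 nm, i.e. at 1680 nm to instrument precision.
* **Image (784 dims).** Grayscale band-window images centered at the three
  reflectance peaks (1070, 1270, 1650 nm; 40-nm windows). The three patches
  are averaged into one, resampled to 28 × 28 by area-weighted block mean,
  and flattened row-major. Averaging before fusion is the only reading
  consistent with the fused dimensionality below (453 + 784 = 1237);
  area-weighting makes the resampling exact for any ROI size, including ones
  not divisible by 28.
* **Fusion (1237 dims).** Concatenation, spectral block first.

Normalization (`feature_normalize()`) is per-feature min-max scaling with
statistics computed on the calibration set and frozen for validation data;
out-of-range validation values are deliberately not clipped, and constant
features map to 0.

## Stacked autoencoder

One autoencoder encodes $y = g(Wx + b_1)$ and reconstructs
$z = g(W^{\top}y + b_2)$ with tied weights, minimizing the mean half squared
reconstruction error $J = \frac{1}{2m}\sum_i \lVert z_i - x_i \rVert^2$.
Layers are pretrained greedily — each on the previous layer's encodings —
then stacked; the last hidden layer's output is the deep feature
(`fit_sae()`, `deep_features()`). When SSC targets are supplied, a linear
head is attached and the encoder plus head are fine-tuned end-to-end against
squared error.

Numerical choices:

* **Activation**: sigmoid throughout. Inputs are min-max scaled to $[0,1]$
  and the decoder must reproduce bounded reflectance, which rules out an
  unbounded output activation. ReLU and a linear hook are available; the
  linear hook exists so tests can verify exact recovery of data on a linear
  manifold (a 3-dim manifold in 20-dim space is driven below 1% of the
  initial loss by a width-3 linear autoencoder).
* **Optimizer**: plain mini-batch gradient descent, fixed learning rate 0.1,
  batch 16, 200 pretraining epochs and 100 fine-tuning epochs by default.
  The per-epoch full-data loss is logged; under these defaults the
  pretraining loss is non-increasing to within 1e-6, which is asserted as a
  property test.
* **Initialization**: uniform $(-r, r)$ with $r = \sqrt{6/(fan_{in} +
  fan_{out})}$, seeded; biases start at zero. Every source of randomness
  (init, batch order, splits, forests) is governed by explicit seeds, and
  identical seeds give bit-identical models.
* **Fine-tuning**: targets are standardized internally (the head stores the
  mean/SD and predictions are mapped back to Brix) so the fixed learning
  rate is independent of the target scale. The head is initialized by
  ridge-stabilized least squares on the pretrained deep features, which
  starts fine-tuning from a sensible convex optimum. Whether fine-tuning
  updates all layers or only the head is exposed as `finetune_scope`
  (default `"all"`); the head-only scope keeps the loss convex and is used
  by the monotone-descent test.
* **Structures**: written `"input-d1-d2-d3"`, e.g. `1237-650-310-130`; three
  stacked autoencoders whose final width (130 here) is the deep-feature
  dimension. The default sweep evaluates three structures per feature kind
  (`default_structures()`).

## Random-forest regression and evaluation

Deep features feed a regression forest (`fit_rf()`, wrapping the
`randomForest` package): bootstrap resamples, `mtry = dim/3`, 500 trees by
default, prediction = mean over trees. Model quality is reported as $R^2$
and RMSE (Brix) on a seeded 90/30 calibration/validation split, stratified
by maturity class so both sets cover the ripeness range
(`split_samples()`). A constant target makes $R^2$ undefined and raises an
error instead of returning 0, so degenerate synthetic configurations cannot
pass silently. `compare_feature_sets()` runs the full
(feature kind × structure) sweep and emits one evaluation row per pair.

## The phantom generator

`generate_phantom()` emulates what the pipeline assumes about a real
acquisition, not the radiometry of any particular sensor:

* a smooth reflectance continuum with peaks near 1070/1270/1650 nm;
* Gaussian absorption bands at 1190 and 1450 nm (inside the high-variation
  1000–1300 nm window and the water-band region) whose depth is **affine in
  SSC** (0.012 reflectance units per Brix) — the monotone SSC–absorption
  link is the signal the regression is supposed to recover;
* a per-fruit **absorption efficiency** factor (relative SD 0.1): fruit
  differ in how strongly a degree Brix absorbs, so the ROI-mean spectrum
  alone does not determine SSC exactly. Without such a nuisance the mean
  spectrum is a sufficient statistic for SSC (per-pixel noise averages out
  over the ROI), spectral-only regression saturates at the ceiling, and
  appending image features can only dilute — an informationally degenerate
  regime far from the one the method targets. Setting this SD to 0 restores
  the degenerate case, which the parameter-recovery tests use deliberately;
* a radial cosine taper making center absorption stronger than rim
  absorption, emulating solids concentrating at the fruit center; the
  taper's amplitude is 30% at the reference 10 Brix and **scales linearly
  with SSC** — riper, sweeter fruit concentrate solids at the center more —
  so the spatial contrast carries SSC information that is independent of
  the per-fruit absorption efficiency. This is the second information
  channel that image and fusion features can exploit and per-pixel maps
  should reveal;
* a per-pixel illumination gain (relative SD 0.05) that multiplies raw and
  white frames alike and therefore cancels exactly under calibration;
* band-dependent Gaussian noise: SD 0.004 in the retained bands and 0.02 in
  the leading/trailing bands (< 942 nm, > 1680 nm), reproducing the noisy
  band edges that motivate trimming;
* background pixels at flat reflectance 0.05 (dark stage), with the
  elliptical fruit mask carried as a cube attribute.

`generate_dataset()` draws SSC from a truncated normal on [6, 14.1] Brix
whose *parent* parameters are solved by moment matching so the **realized**
distribution has mean 9.29 and SD 2.17 — treating the published summary
statistics as properties of the sample rather than of an unobservable
untruncated parent (the raw-parameter reading would inflate the realized
mean to ≈ 9.51). Maturity labels (30 immature / 50 semi-mature / 40 mature
per 120) are assigned by ascending SSC, since only counts and ranges are
known per class; the class-specific ranges 0–8.5 / 0–11 / 0–13.2 Brix are
used as pseudo-color rendering ranges, not as generation constraints.

What phantoms deliberately do **not** model: sensor-specific radiometry,
specular highlights and fruit-surface curvature effects, biochemical
covariates (acidity, water content) that correlate with SSC in real fruit,
and scattering-driven baseline shifts. Passing tests therefore demonstrate
that the pipeline recovers a monotone absorption signal embedded in noise
with the stated geometry, and that fused spectral + spatial features match
or beat spectral-only features when both channels are informative — not
field performance on real fruit.

## Pixel-wise SSC maps

`pixelwise_predict()` pushes every masked pixel's trimmed, normalized
spectrum through the SAE encoder and the forest. Only spectral-feature
models are admissible per pixel: a fusion model requires a whole-fruit
image vector, which has no per-pixel meaning, and is rejected with an
incompatible-model error. Pixel spectra are normalized with the frozen
calibration-set statistics, not per-pixel statistics. Rendering
(`render_pseudocolor()`) composes the RGB raster directly (palette lookup,
neutral-gray background, a color bar annotated with the maturity range via a
small built-in bitmap font) and writes it with `png::writePNG`, so identical
maps yield byte-identical files — no graphics device is involved.

Note that per-pixel predictions on phantoms sit slightly above the
whole-fruit value at the center and below it at the rim: the model is
trained on ROI-mean spectra, while individual pixels carry the full spatial
gradient. The map's job is the spatial pattern, and the center-minus-rim
ordering is what the tests assert.

## Problem sizes used in tests

The package's tests and the acceptance script run the full 120-sample study
design (90/30 split, nine-structure sweep) but generate phantoms at reduced
spatial size (48 × 48 or 64 × 64 pixels with the full 508-band axis, ROI
sizes 18–24) and reduced epoch counts (40 pretraining / 25 fine-tuning in
the sweep), chosen so a desk-scale run finishes in minutes while leaving the
band accounting, feature dimensions and statistical behavior identical to
the full geometry. Spatially larger phantoms only add pixels to the ROI
mean, which concentrates it further around the designed spectrum; they do
not change any dimension the pipeline reasons about. Where a test needs the
full 636 × 838 frame geometry (ROI placement) it uses a cube with few bands
instead.

## Known limitations

* The SAE is trained by fixed-rate gradient descent; there is no adaptive
  optimizer, early stopping, or regularization beyond the seeded
  initialization. This is adequate for the desk-scale problems here but not
  tuned for large real datasets.
* Fusion features append a 784-dim image block to a 453-dim spectral block
  without reweighting; with min-max scaling both blocks land in $[0,1]$, but
  the image block has more coordinates and can dominate distance-based
  learners. When the spectral channel alone is (near-)sufficient for SSC,
  fusion brings no information and the extra coordinates slightly *hurt*
  forest accuracy through feature-subset dilution; fusion's advantage
  appears when part of the SSC signal is only spatially expressed.
* ENVI support covers BSQ/BIL float64 with wavelengths in the header —
  the subset the pipeline itself writes; BIP and integer payloads are out
  of scope.
* Phantom realism is limited to what the estimator assumes (see above);
  conclusions about real-fruit accuracy require real calibrated data.
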