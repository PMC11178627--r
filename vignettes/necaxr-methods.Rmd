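---
title: "Enhancement and augmentation pipelines for abdominal radiographs: methods and design"
author: "necaxr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enhancement and augmentation pipelines for abdominal radiographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(necaxr)
```

## The problem

Necrotising enterocolitis (NEC) is a severe intestinal disease of premature
neonates. Staging it from abdominal radiographs (AXRs) is hard: the
radiological signs — mottled intramural gas, free sub-diaphragmatic air —
are subtle, low-contrast, and easily confounded. Datasets are small because
the disease is rare, so any classifier built on AXRs leans heavily on two
levers: *stochastic augmentation*, which artificially diversifies a small
training set, and *deterministic preprocessing*, which enhances the image
attributes (local contrast, edges) that carry the diagnostic signal.

`necaxr` implements both levers as a tested library: a suite of seedable
augmentations with per-draw application chances, a family of enhancement
operators built from their mathematical definitions, two composed
preprocessing pipelines that turn a single-channel radiograph into the
three-channel input a convolutional backbone expects, a synthetic phantom
generator that stands in for clinical data, and a stratified
cross-validation harness that measures what the pipelines buy.

## Image model

All operators work on a `GrayImage`: a matrix of finite intensities in
[0, 1], row-major, origin top-left, bright = more attenuating tissue.
Readers normalise by the *container* bit depth (8- or 16-bit full range),
not the observed min/max, so identical scenes at different exposures remain
distinguishable. DICOM frames are the exception: after applying rescale
slope/intercept they are windowed to the stored min/max (there is no
universal absolute scale across modalities), and `MONOCHROME1` data are
re-inverted to the bright-tissue convention. A frame with zero dynamic
range reads as all zeros with a warning rather than an error, so batch
conversions survive degenerate files.

## Enhancement operators

Each operator is defined by a closed formula and checked in the test suite
against an independent brute-force oracle (nested-loop convolution, dense
linear solve, sort-based percentiles).

* **Sharpening** — correlation with an intensity-preserving 3x3 kernel
  (entries sum to 1; default `[[0,-1,0],[-1,5,-1],[0,-1,0]]`, the classic
  Laplacian sharpen), symmetric boundary extension, clipped to [0, 1].
  Symmetric (edge-repeating) boundaries avoid the dark frame artefacts
  that equalisation would amplify.
* **Histogram equalisation** — the textbook CDF mapping
  `(cdf(v) - cdf_min)/(1 - cdf_min)` over 256 bins. A constant image is
  returned unchanged: the formula degenerates to 0/0 and identity is the
  least surprising resolution. The mapping is monotone and idempotent up
  to binning (within `2/nbins`).
* **CLAHE** — per-tile clipped-histogram equalisation with the clipped
  excess redistributed uniformly, blended by bilinear interpolation of the
  four surrounding tile mappings. Defaults (8x8 tiles, clip limit 2.0
  relative to the mean bin height, 256 bins) are the ubiquitous settings
  in the literature. One unclipped tile reduces exactly to global
  equalisation; degenerate tiles map by identity.
* **Percentile compression** — dynamic-range normalisation mapping the 2nd
  and 98th intensity percentiles to 0 and 1. "Histogram compression" is
  not a standardised operator name; this percentile-clip reading is a
  documented package choice.
* **Unsharp masking** — `img + amount * (img - blur(img, sigma))` with a
  separable Gaussian truncated at radius `ceil(3*sigma)`; `amount = 0` is
  the exact identity.
* **Illumination-map enhancement (LIME)** — the initial illumination map
  of a single-channel image is the image itself, floored at `epsilon`.
  The refined map solves the sparse SPD system
  `(I + alpha * sum_d D_d' W_d D_d) t = t_hat` with forward differences
  `D_d` (replicated boundary) and edge-aware weights
  `1/(|grad t_hat| + epsilon)` computed once from the initial map (the
  first-order approximation of the original method's sped-up solver; the
  iterated exact optimisation is out of scope). The system is solved by
  sparse Cholesky; the contract is the relative residual (<= 1e-8), not
  the algorithm. The output divides the image by the gamma-corrected map
  (`gamma = 0.8`), so with `gamma <= 1` no pixel darkens. Defaults
  `alpha = 0.15`, `epsilon = 1e-3` follow the settings reported for the
  original method.

## The two pipelines

* **Pr-1 (contrast-centred)**: sharpen, then equalise, both applied
  deterministically (100% likelihood), replicated to three channels. The
  order is a package decision — sharpening first means equalisation
  normalises the *final* histogram rather than having its output
  re-distorted by a later convolution.
* **Pr-2 (edge-centred)**: three differently processed planes — channel 0
  sharpened; channel 1 sharpened then CLAHE; channel 2 percentile
  compression, unsharp masking, then illumination enhancement, in that
  listing order. On any non-constant input the three channels are
  pairwise distinct; both pipelines are bit-deterministic.

On a constant image `c`, Pr-2's third channel evaluates to
`c^(1 - gamma)`: compression and unsharp masking are identities on
constants and the refined illumination map equals the constant itself.
This equals 1 exactly only at `gamma = 1`; the package documents and
tests the general closed form rather than the special case.

## Augmentation suite

Ten augmentations (translation, cropping, rotation, horizontal/vertical
flips, occlusion, additive Gaussian noise, equalisation, sharpening,
inversion) are wrapped in `AugmentSpec` (name, chance `C`, magnitude) and
applied in policy order, each gated by an independent uniform draw against
its chance. Magnitudes are *maxima*, sampled per application (a 10%
translation limit draws shifts uniformly in ±10% of each dimension), which
matches standard augmentation practice. Fill value for vacated pixels is
0, matching the collimated black border of radiographs. Published settings
tables conflate the chance column with magnitude settings; this package
resolves the ambiguity by applying magnitude-type augmentations
(translation, cropping, rotation, occlusion) with chance 1 when enabled
and using the stated chance for the rest (`standardPolicy()`). The noise
model is zero-mean Gaussian with sd 0.05 on the [0, 1] scale — the
amplitude is unspecified in the source literature and 0.05 is a visible
but non-destructive perturbation for radiographs.

A policy application is a pure function of `(image, seed)`: the draw plan
(gates, shifts, angles, noise field) is materialised first and then
replayed, which is also how the three channels of a preprocessed stack
stay geometrically aligned (`applyPolicyMulti()`).

## Synthetic phantoms

`generatePhantom()` renders a stylised neonatal AXR: dark background
(0.05), bright body ellipse (0.55), brighter spine column (0.75), and
6–10 jittered elliptical bowel-gas lucencies (≈ −0.15). The whole
anatomy sits at a per-image positioning offset (uniform within ±3% of
the frame): mobile neonatal radiographs never show the patient at a
pixel-identical position, and without this variability any evaluation
of translation augmentation would be meaningless — a model trained on
shifted copies of perfectly centred anatomy is tested on a distribution
it never saw. Class-specific
additions: mNEC gets 3–6 clusters of small mottled lucencies inside the
bowel region at `-lesionContrast * 0.3`; sNEC gets one large
sub-diaphragmatic lucent crescent at `-lesionContrast * 0.4`; NP gets
nothing. The scene is blurred (sigma 1.2 px, a mild system blur), noised
(default sd 0.05), and clipped. Scene, lesion and noise draws come from
three sub-streams of the spec seed, so a lesion class at contrast 0 is
pixel-identical (before noise) to the NP phantom with the same seed.
Ground-truth lesion masks are persisted so enhancement can be scored
without any classifier.

Defaults — 224x224 frame, lesion contrast 0.35, noise 0.05 — are the
package's study conditions: contrast 0.35 makes the lesions faint against
the bowel texture (the clinical problem is precisely that the signs are
subtle), and they were frozen before the evaluation harness was run.
The phantoms are *stylised, not anatomically realistic*: they have no
patient-level correlation, no scatter or beam-hardening physics, no pose
variation. Passing tests therefore demonstrate that the operators and the
harness behave as specified on controllable class structure — not that
any accuracy level transfers to clinical radiographs.

Separability is calibrated, not assumed: a multinomial logistic classifier
on 15 pixel-statistics features (global moments and quantiles, plus
low-tail quantiles and a high-pass "mottling" score over the two fixed
anatomical zones where lesions occur) exceeds 90% five-fold accuracy at
contrast 0.8 / noise 0.02, and its accuracy rises monotonically with
lesion contrast. The generator amplitudes were frozen once this held.

## Evaluation harness

`makeFolds()` deals each label's shuffled images round-robin into `k`
folds (per-label counts differ by at most one; 320 per label with `k = 5`
gives exactly 64 per label per fold). Metrics are accuracy and
macro-averaged precision/recall/F1 — macro because the classes are
balanced (macro ≈ weighted) and it is the stricter convention; a class
with no predictions scores precision 0 rather than NaN.

The desk-scale backbone is a small convolutional network: four blocks
of 3x3 convolution (zero padding), ReLU and 2x2 mean pooling (filter
counts 8/16/32/32), global average pooling and a softmax head, trained
from scratch with Adam at batch size 16 and the argmax class decision of
the full-scale protocol. Weight sharing matters here: without it (an MLP
on flattened pixels, still available as `backbone = "mlp"`), translation
augmentation turns into pure train/test mismatch and inverts the
protocol's logic. The learning rate defaults to 0.003 rather than the
full-scale protocol's 0.001: that value is tied to fine-tuning a
pretrained deep network, while a small from-scratch CNN is still far
from converged at 0.001 within any reasonable epoch budget (the choice
was made on convergence of the training curves, applied identically to
every arm of a comparison). Inputs are standardised per channel with
training-fold statistics. The convolution kernels are compiled
(im2col + BLAS products), with gradients verified against central
finite differences.

Images are resized to the 32x32 working resolution *first*
(anti-aliased: Gaussian prefilter at half the scale factor, then
bilinear), and the preprocessing pipeline runs at that resolution —
preprocessing operates on the raster the classifier actually sees, and
its output is cacheable because it is deterministic per image.
Augmentation then runs per image per epoch on the preprocessed stack.

`compareRuns()` reports the accuracy delta against a baseline report and
a two-sided Welch t-test over per-fold accuracies. Fold variances are
floored at 1e-12 so a zero-variance comparison still yields a decision
(identical means give p = 1). Welch's test is a package choice; the
source protocol reports significance without naming a test.

Problem sizes used by the shipped evaluation: 300 phantoms (100 per
class), 5 folds, 50 epochs, 2–3 harness seeds — sizes chosen so the whole
evaluation runs comfortably on one CPU while the directional comparison
(preprocessing + translation vs baseline) remains stable across seeds.

## Numerical choices and degenerate inputs

* Boundary handling for every convolution: symmetric (edge-repeating).
* Histogram bin of intensity `v`: `min(floor(v * nbins) + 1, nbins)` —
  the top bin is closed so `v = 1` is not out of range.
* Resizing: corner-aligned bilinear (resizing to the same shape is the
  exact identity); rotations snap coordinates within 1e-9 of a grid point
  so quarter-turns and full turns lose no boundary pixels.
* Constant images: equalisation, CLAHE and percentile compression return
  them unchanged; unsharp masking and sharpening preserve them by
  construction.
* All stochastic components draw from explicitly seeded local RNG streams
  that are restored afterwards; no global RNG state leaks.

## Known limitations

* The phantom generator makes no claim of anatomical realism; results on
  it bound what the code does, not what clinical accuracy would be.
* LIME here is the single-channel, first-order weighted-quadratic variant;
  the original colour channel-max initialisation and iterated exact
  optimisation are out of scope.
* The DICOM reader handles uncompressed little-endian single-frame files
  only — enough for test fixtures and simple exports, not a general
  clinical archive client.
* At the default phantom noise (sd 0.05), sharpening amplifies pixel
  noise by `sqrt(sum(k^2)) ≈ 5.4`, which *lowers* the lesion
  contrast-to-noise ratio of the sharpened/CLAHE channel relative to the
  raw image even though it raises edge salience; the CNR gain of that
  channel materialises only at low noise (≲ 0.01). The package reports
  this honestly rather than tuning the generator's noise down.
* The phantoms' positional variability (±3% of the frame) is small
  compared with the 10%-of-length translation augmentation, so on
  phantom data the benefit of translation augmentation is bounded and
  pipeline-vs-baseline comparisons land within seed-to-seed noise; on
  clinical mobile radiographs, whose positioning varies far more, the
  augmentation has correspondingly more to contribute.
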