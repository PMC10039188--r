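---
title: "Segmentation-based wrist fracture detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmentation-based wrist fracture detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristseg)
```

## The problem and the approach

Distal radius fractures are among the most common fractures seen in
emergency departments, and their diagnosis rests on correct reading of a
two-view wrist examination: one postero-anterior (PA) and one lateral
radiograph. `wristseg` implements a *segmentation-based* detector: a
convolutional network is trained on pixel-level fracture annotations and
emits a per-pixel fracture probability (a confidence map) for each
radiograph. The image-level decision is simply whether the maximum
confidence anywhere in the radiograph reaches an operating threshold, and
the examination-level decision combines the two views. Compared with
whole-image classifiers, the segmentation route indicates *where* the
network sees a fracture without post-hoc attribution methods, which
matters clinically.

The package covers the complete pipeline: synthetic data generation (real
emergency-department radiographs cannot be redistributed), deterministic
preprocessing, exact tiling arithmetic for a valid-padding U-Net,
from-scratch training, shift-and-average test-time ensembling, and the
diagnostic evaluation layer (confusion matrices, sensitivity/specificity
panels with confidence intervals, likelihood ratios, post-test
probabilities, bootstrap ROC/AUC, Cohen's kappa).

## The synthetic radiograph simulator

No clinical images ship with the package; every stage is exercised on
simulated two-view examinations from `synth_config()` /
`generate_dataset()`. A simulated wrist radiograph consists of:

* a darker soft-tissue background with a gentle intensity gradient and a
  random per-image exposure offset;
* two quasi-parallel bright bands (the radius and ulna analogue) with
  brighter cortical margins -- enough structure for CLAHE and the network
  to do nontrivial work without anatomical modelling;
* for fracture cases, a dark *lucent* crack: a jittered polyline crossing
  the radius band, rendered as a smooth multiplicative attenuation
  (transmission through the gap retains ~30% of the local intensity at the
  crack core). Multiplicative rather than subtractive darkening keeps the
  crack visible whatever it crosses -- bone interior, cortex, overlapping
  bones in the lateral view, or a cast -- so the ground truth never marks
  an invisible fracture. The mask is the exact dilation of the polyline to
  `crack_width_px` (default 3 px), matching how a clinician outlines a
  fracture line;
* optionally a broad semi-transparent band that raises intensity over part
  of the image (a cast analogue);
* Gaussian blur (`blur_sigma_px`, default 0.7) and additive Gaussian noise
  (`noise_sd`, default 40 on the 12-bit scale).

Intensities are generated on a 12-bit-like 0--4095 scale so the
normalization step is exercised nontrivially. Label frequencies default to
the cohort structure of the clinical study the package models: fracture
prevalence 0.7 and cast rate 0.45. Both views of an examination share the
labels but are rendered independently; no cross-view geometric consistency
is attempted, because the detector treats views as separate network
inputs.

What the simulator deliberately does *not* emulate: real anatomy,
projection physics, fracture-type taxonomies, pediatric physes, or the
hard ambiguous cases that drive clinical error rates. A model that
performs well on this synthetic task demonstrates that the pipeline's
mechanics (geometry, training, decision rules, statistics) are correct --
not that the approach reaches any particular clinical accuracy.

## Preprocessing

Fixed order: resample, CLAHE, normalize.

1. **Resampling** to an isotropic physical resolution (default
   0.1 x 0.1 mm) with bilinear interpolation; output size is
   `round(size * spacing / target)` per axis. Masks travel with nearest
   neighbour and stay binary. Pixel spacing is mandatory metadata -- NIfTI
   headers or PNG sidecars must carry it.
2. **CLAHE** (contrast-limited adaptive histogram equalization): per-tile
   histograms over 256 bins of the observed range, clipped at a fraction
   of the tile pixel count with the excess redistributed, mappings blended
   bilinearly between tile centers. Tile grid and clip limit are not
   dictated by the modelled study; the defaults (8 x 8 tiles, clip 0.01 of
   the tile pixel count) follow common practice and are exposed in
   `preprocess_config()`. Images whose dimensions are not divisible by the
   grid are mirror-padded for the equalization and cropped back. A
   constant image passes through unchanged.
3. **Normalization**: per-image min--max to `[0, 1]`; a constant image
   maps to zeros. Per-image (rather than per-dataset) scaling removes
   manufacturer intensity-scale differences.

## Valid-padding geometry

All convolutions are 3 x 3 with *valid* padding: each one shrinks the
tensor by 2 px per axis, each of the 7 poolings halves it (requiring an
even size), each upsampling doubles it. Consequently only a sparse set of
input sizes is feasible, and the input must be substantially larger than
the output. `output_size_given_input()` simulates a size through the
network; `required_input_size()` inverts it.

Under the default geometry -- one convolution per encoder stage including
the bottleneck (8), two per decoder stage (12), and five in the top
decoder stage (the two stage convolutions plus three final convolutions),
25 in total -- feasible outputs form the progression ..., 126, 254, 382,
... (stride 128). The working tile is 130 x 130 output pixels, so
inference uses the smallest feasible configuration at least that large:
a 1278 x 1278 input window producing a natural 254 x 254 output that is
center-cropped to the 130 x 130 tile (margin 574 px per side).

Tiling: output tiles lie on a regular 130-px grid covering the image; the
last row/column of tiles is shifted inward when the image size is not a
multiple of 130, and the doubly-covered strip is owned by the later tile
-- a deterministic tie-break that makes stitching an exact partition
(every pixel written by exactly one tile, bit-exactly). Input windows are
read from a mirror-padded image; mirroring avoids the intensity
discontinuities zero-padding would create under valid convolutions.

**Shift-and-average**: tiled inference is repeated with the tile grid
shifted by all offsets in `{0, 26, 52, 78, 104}^2` -- 25 passes, since
5 x 26 px tiles the 130-px patch period exactly -- and the 25 confidence
maps are averaged. Whether one shifts the image or the grid is equivalent
up to border handling; the grid-shift reading is implemented (the image is
mirror-padded at the top-left by the offset and the result cropped back).
For a translation-equivariant model the ensemble is a no-op, which is a
test oracle; for a real tiled model it averages out tile-boundary
artifacts.

## The network

`network_spec()` describes the U-Net variant declaratively: 25
convolutional layers, 7 max-pooling and 7 upsampling steps, skip
connections center-cropped to the decoder size at each level. Every hidden
convolution carries batch normalization and ReLU; the final convolution
maps to one channel read through a sigmoid. Dropout (rate 0.5) precedes
the three final convolutions. Channel widths are not dictated by the
modelled architecture description; the default starts at 16 and doubles
per level, capped at 256, and is exposed because desk-scale CPU training
wants narrower models.

The **auxiliary head** is a patch-level fracture classifier used only
during the second training phase and never at inference: global average
and global max pooling are applied to the bottleneck output and the
outputs of succeeding decoder stages (default taps: bottleneck plus the
two deepest decoder stages -- the tap set is configurable since the
original description shows only its first three connections),
concatenated, and passed through four hidden fully connected layers of
halving width to a single sigmoid unit. Descriptions of "four fully
connected layers and a single output neuron" versus "five FC layers" are
reconciled as 4 hidden layers + 1 output unit.

No deep-learning framework is involved: the layers, batch-norm statistics,
dropout, backpropagation and the Adam optimizer are implemented in the
package (the tensor kernels in C++), which keeps the build fully
self-contained and every numerical choice inspectable. Gradients are
verified against finite differences in the test suite.

## Two-phase training

Phase 1 trains the segmentation path alone: Adam, learning rate 0.001,
per-pixel binary cross-entropy. Phase 2 attaches the auxiliary head and
continues at learning rate 0.0025 on the *sum* of the segmentation and
auxiliary cross-entropies for three epochs; the auxiliary target of a
patch is whether the fracture drawing intersects its output window.
Validation is an examination-wise random 10% split. Two readings of
"validation accuracy did not improve after five epochs" are honoured
jointly: phase 1 uses patience-based stopping (patience 5 epochs) *and* a
five-epoch cap, the modelled schedule's actual length.

Two distinct "accuracies" appear and are both logged: the training monitor
is pixel-level segmentation accuracy at confidence 0.5, while the
operating threshold is chosen later by `select_threshold()` to maximize
*image-level* accuracy of the max-confidence rule on the validation split
(ties break toward the largest, most specific threshold). The returned
checkpoint is the best-validation-pixel-accuracy epoch.

Patches are the tiles of each image, every tile of every image once per
epoch in a seeded shuffle; optional oversampling of fracture-containing
patches is off by default. The training target of a patch is the
130 x 130 output-tile core (the logits' natural 254 x 254 footprint is
center-cropped for the loss), which keeps the loss region, the auxiliary
target and tiled inference mutually consistent.

## Decisions and evaluation

A radiograph is called positive iff its maximum confidence is **at or
above** the threshold (the modelled operating point is 0.61; inclusive
comparison). Examinations combine views by either of two rules, both
always reported: *either* view above threshold, or the *mean* of the two
view maxima above threshold.

The metric panel (sensitivity, specificity, accuracy, PPV, NPV) uses Wald
(normal-approximation) 95% intervals truncated to `[0, 1]` -- chosen
because it reproduces the printed intervals of the modelled study's
tables, and documented as swappable. Likelihood ratios use the log-method
interval. Zero-denominator metrics are reported as undefined (`NA`), never
as zero. Post-test probabilities use the odds form with a pre-test
probability of 0.47. ROC curves sweep the observed confidences; AUC is the
trapezoidal area (identical to the normalized Mann--Whitney statistic,
which is the cross-check in the tests); the AUC interval is a percentile
bootstrap (default 1e5 replicates, scalable down) resampling *
examinations* -- the natural independence unit, since the two views of a
wrist are correlated. Cohen's kappa with marginal-product expected
agreement covers interrater reliability.

`evaluate_testset()` reports five strata (all radiographs, lateral only,
PA only, either-rule examinations, mean-rule examinations) for all cases
and the no-cast subgroup, plus an optional per-group (e.g. manufacturer)
confusion breakdown whose rows partition the totals.

## Desk-scale study sizes and their rationale

The test suite and the acceptance script run everything at desk scale,
chosen once:

* unit tests use a two-pool "tiny" geometry (input 50 -> output 28) and
  64 x 64 synthetic images, where a training run takes seconds;
* the end-to-end study simulates **80 examinations** of 130 x 130 px
  (one output tile per view), trains the **default 25-layer / 7-pool
  geometry** with `base_channels = 2` (reduced width; the full-width
  default is CPU-hostile at no benefit on synthetic data), and uses
  **batch size 2**: with 108 training patches per epoch and the fixed
  5 + 3-epoch schedule, batch 2 yields roughly 430 optimizer updates --
  enough for Adam to move a randomly initialized network, whereas batch 8
  would yield only ~100 updates at identical compute. Held-out
  discrimination is measured on 20 examinations at the examination level
  (mean-rule score).

The no-cast/cast split, prevalence and noise levels stay at the generator
defaults throughout; they are study conditions, not tuning knobs.

## Numerical choices

* Batch norm: eps 1e-5, running-statistic momentum 0.1; biased (population)
  variance within a batch, running statistics at inference.
* Adam: beta1 0.9, beta2 0.999, eps 1e-8; bias-corrected.
* Initialization: He-scaled Gaussians, seeded; batch-norm scale 1, shift 0.
* Binary cross-entropy is computed on logits in the numerically stable
  form `max(z, 0) - z y + log(1 + exp(-|z|))`.
* Skip-connection center crops use floor offsets when the size difference
  is odd.
* All randomness (labels, rendering, splits, shuffles, dropout, bootstrap)
  flows through explicit seeds; identical seeds reproduce datasets,
  training histories and parameters bit-identically within one software
  environment.

## Known limitations

* The clinical accuracy figures of the modelled study are not reproducible
  here: the hospital data and trained weights are unavailable, and the
  synthetic task is far easier than real radiography. End-to-end tests
  demonstrate mechanism, not clinical performance.
* DICOM input is recognized but unsupported (no reader available to the
  package); the supported lossless route is NIfTI, which is also the
  modelled workflow's conversion target.
* PNG output is 8-bit (plus sidecar scale); NIfTI is the lossless
  container for images and confidence maps.
* The per-stage distribution of the 25 convolutions and the auxiliary tap
  set are underdetermined by the architecture's published description;
  both are configuration with documented defaults satisfying every stated
  count.
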