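# wristseg

Segmentation-based detection of distal radius fractures in two-view wrist
radiograph examinations.

Distal radius fractures account for a large share of emergency-department
imaging, and misreading wrist radiographs is a recognized source of
diagnostic error. `wristseg` implements a fracture detector built on
*semantic segmentation*: a valid-padding U-Net is trained on pixel-level
fracture annotations and emits a per-pixel fracture probability
(confidence map) for each radiograph, so the model shows *where* it sees a
fracture rather than only *that* it sees one. The package is aimed at
researchers studying segmentation-based diagnostic pipelines: it contains
every stage — simulation, preprocessing, exact tiling arithmetic,
training, ensembled inference, and the diagnostic statistics — as tested,
reusable R functions.

## The model in brief

* **Decision rule.** For a radiograph with confidence map
  $C(x) \in (0,1)$, the image-level decision is
  $\max_x C(x) \ge t$ with operating threshold $t$ (default 0.61, chosen
  on validation data by maximizing accuracy). An examination (one
  postero-anterior + one lateral view) is positive under the *either* rule
  if either view fires, or under the *mean* rule if the mean of the two
  view maxima reaches $t$.
* **Network.** A U-Net variant with 25 convolutional layers (3×3, valid
  padding, batch norm, ReLU) and 7 max-pooling/upsampling steps with
  center-cropped skip connections. Valid padding forces inputs larger than
  outputs: a 130×130 output tile requires a 1278×1278 mirror-padded input
  window. Training is two-phase (Adam, lr 0.001 then 0.0025): phase 2
  attaches an auxiliary patch classifier (global average+max pooling of
  deep feature maps, FC layers, one sigmoid unit) and minimizes the summed
  binary cross-entropy; the head is discarded at inference.
* **Shift-and-average.** Tiled inference is repeated at 26-pixel grid
  shifts (5×5 offsets = 25 passes) and the confidence maps are averaged.
* **Evaluation.** Sensitivity, specificity, accuracy, PPV, NPV with Wald
  95% CIs; likelihood ratios $LR^+ = \mathrm{sens}/(1-\mathrm{spec})$,
  $LR^- = (1-\mathrm{sens})/\mathrm{spec}$ with log-method CIs; post-test
  probabilities from pre-test odds; ROC/AUC with an examination-level
  percentile bootstrap; Cohen's kappa for rater agreement.
* **Synthetic data.** Clinical radiographs cannot be redistributed, so
  `generate_dataset()` simulates two-view examinations: bright radius/ulna
  bands with cortical edges on soft-tissue background, dark crack-shaped
  lucent lines with exact ground-truth masks, optional cast overlays,
  blur and noise, 12-bit-like intensities, fracture prevalence 0.7.

The layer kernels (valid convolution, pooling, upsampling) are implemented
in C++ inside the package; no external deep-learning framework is needed.

## Worked example

Evaluation layer on a published-scale confusion matrix (fracture = positive
class; 499/43 fracture row, 27/203 normal row):

```r
library(wristseg)
cm <- confusion_matrix(tp = 499, fp = 27, tn = 203, fn = 43)
diagnostic_metrics(cm)
#> sensitivity  0.92 (0.90-0.94)
#> specificity  0.88 (0.84-0.92)
#> accuracy     0.91 (0.89-0.93)
#> ppv          0.95 (0.93-0.97)
#> npv          0.83 (0.78-0.87)
#> lr_pos       7.8 (5.5-11)
#> lr_neg       0.09 (0.067-0.12)
```

The printed panel reads: of 542 fractured radiographs the detector found
92%, of 230 normals it cleared 88%, and a positive call is right 95% of
the time at this prevalence. Likelihood ratios translate the operating
point into evidence strength; with a pre-test fracture probability of
0.47, `posttest_probability(0.47, 7.8)` gives `0.87` — a positive result
raises the fracture probability from 47% to 87%.

Geometry and a small synthetic round trip:

```r
g <- unet_geometry()                        # 25 convs, 7 pools, valid padding
required_input_size(g, 130)
#> $input_px
#> [1] 1278
#>
#> $actual_output_px
#> [1] 254

cfg   <- synth_config(image_height_px = 130, image_width_px = 130, seed = 1)
exams <- lapply(generate_dataset(4, cfg), preprocess_exam)
spec  <- network_spec(g, base_channels = 2)     # desk-scale width
model <- build_model(spec, seed = 1)
map   <- predict_confidence_map(model, exams[[1]]$pa$pixels)
dim(map)
#> [1] 130 130
```

`train_two_phase()` runs the full two-phase schedule on such a dataset and
returns the best-validation checkpoint plus its training history;
`predict_exams()` + `evaluate_testset()` produce the stratified diagnostic
report. A thin command-line wrapper with `simulate`, `preprocess`,
`train`, `predict` and `evaluate` subcommands ships in `inst/cli/wristseg`.

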