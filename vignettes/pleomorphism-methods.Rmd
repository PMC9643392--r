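---
title: "Scoring nuclear pleomorphism as a continuous spectrum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring nuclear pleomorphism as a continuous spectrum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Nuclear pleomorphism — the degree of abnormality in the size, shape and
chromatin appearance of tumor nuclei relative to normal breast epithelium —
is one of the three components of breast-cancer grading. Unlike mitotic
count or tubule formation it has no quantitative definition, which makes it
the least reproducible of the three components across pathologists.
`pleospectrum` implements a fully automated scoring pipeline that treats
pleomorphism not as a three-way classification but as a **continuous
severity score on [1, 3]**, learned by a convolutional regressor from
reference labels built by average-pooling the discrete scores of a rater
panel. Averaging a panel keeps the information carried by the *spread* of
the raters' scores: an item scored `2,2,2` and an item scored `1,2,3` have
the same majority but different means only by chance, and items scored
`2,3,3` versus `3,3,3` get genuinely different continuous labels.

Because clinical whole-slide images cannot ship with a package, every
stage is developed and validated on a **synthetic histology generator**
with complete ground truth. The pipeline, its training protocol and its
evaluation harness are nevertheless written exactly as they would run on
real H&E rasters.

## The pipeline

1. **Cell detection** (`detectCells`): point detections of epithelial
   cells, each labeled tumor or normal with a confidence. This mirrors a
   two-stage design in which a frozen detection network gates everything
   downstream: only its *output contract* matters here, so the package
   offers an `oracle` mode (ground-truth passthrough, for closed-loop
   validation) and a `blob` mode (multi-scale Laplacian-of-Gaussian
   detection on the hematoxylin optical-density channel, with a
   radius-threshold tumor/normal classifier).
2. **Density-guided patch sampling** (`densityMap`,
   `samplePatchCenters`): Gaussian-smoothed detection density steers
   training patches toward areas of high nuclear composition,
   proportionally to density rather than by a hard threshold.
3. **Dense-block regressor** (`buildRegressor`, `trainRegressor`): a
   DenseNet-style convolutional network — dense blocks whose layers
   receive the concatenation of all preceding feature maps, 1x1
   transition layers with average pooling between blocks, global average
   pooling, and one linear output. Training minimizes the smooth-L1 loss
   between the raw (unclamped) output and the continuous reference score,
   with Adam plus decoupled weight decay, a plateau learning-rate
   schedule (times 0.7 after 10 stagnant validation epochs) and early
   stopping (10 stagnant epochs). Predictions are clamped to [1, 3] only
   at inference.
4. **Slide inference** (`tileGrid`, `scoreSlide`): the slide is scored as
   overlapping tiles (reference geometry: 512-px tiles with 448-px
   overlap); every 64-px block averages the scores of all tiles covering
   it, and the slide score is the mean over tumor-masked blocks. The
   block map renders as a green-yellow-red heatmap (`renderHeatmap`).
5. **Quantization and agreement** (`quantize`, `quadraticKappa`,
   `pairwiseKappaReport`): continuous scores are quantized into `p` even
   brackets of [1, 3] for comparison with discrete rater panels via
   Cohen's quadratic weighted kappa, majority votes with
   confidence-weighted tie-breaking, and leave-one-out majorities.

## The synthetic generator

`generateNucleusField` draws nuclei as a hard-core point process (minimum
centre distance 0.8 times the sum of two minor semi-axes — nuclei touch
but do not pathologically overlap) at a target density of 6000 nuclei/mm²
for tumor and 5000/mm² for normal epithelium, values in the range of
cellular breast carcinomas. Severity `s` drives morphology through a
linear map, chosen once so that the extremes are visually and
statistically separable while mid-range patches remain genuinely
ambiguous:

| parameter | s = 1 | s = 3 | role |
|---|---|---|---|
| mean equivalent radius | 3.0 µm | 5.5 µm | nuclear enlargement |
| radius CV | 0.10 | 0.45 | anisonucleosis (size variation) |
| mean minor/major ratio | 0.90 | 0.50 | elongation / irregularity |
| chromatin contrast | 0.15 | 0.65 | coarse chromatin texture |

Every summary statistic a scorer could use (mean area, area CV, mean
eccentricity, contrast) is strictly increasing in `s`; the package's test
suite verifies this monotonicity over a severity grid. `renderPatch`
draws soft-edged ellipses of hematoxylin optical density, modulated by a
per-nucleus cosine-wave chromatin texture, over a uniform eosin
background (Beer-Lambert absorption with the standard Ruifrok-Johnson
stain vectors), plus Gaussian read noise of 4/255 — enough to make blur
and noise augmentation meaningful.

What the generator does **not** emulate: stromal texture, lymphocytes and
other non-epithelial cells, tissue folds, stain variability between
"scanners", out-of-focus regions, nucleoli. Passing tests therefore show
that the pipeline's machinery is correct and that the regressor can
recover a morphology-encoded severity signal — not that it grades real
slides at pathologist level.

## Observer panel model

`simulatePanel` scores item *i* by rater *g* as the three-bracket
quantization of `clamp(s_i + bias_g + e, 1, 3)`, `e ~ N(0, sd_g)`. The
default panel (`raterPanel(10)`) spreads biases over [-0.25, 0.25]
severity units and noise standard deviations over [0.25, 0.45] — chosen
once to produce the kind of imperfect-but-substantial agreement real
panels show, with distinct stricter/looser and steadier/noisier raters.
Reported confidence falls with the distance of the perceived severity to
the nearest bracket edge (certain beyond 0.20, fairly certain beyond
0.08): raters are unsure exactly when their percept is near a boundary.

Majority voting breaks ties by the larger sum of ordinal confidence
weights (1/2/3) among tied categories; residual ties go to the category
nearest the panel mean and then to the lower category. The confidence
rule is the field's convention; the residual cascade is this package's
own deterministic choice and is deliberately explicit because silent
tie-breaking is a classic source of irreproducible kappas. An undefined
kappa (both raters constant: zero chance-expected disagreement) is
signalled as `NA` with a typed warning, never silently mapped to 0,
because a silent zero would corrupt mean-kappa summaries.

## Quantization

The range [1, 3] is partitioned into `p` even brackets with exact edges
`1 + 2k/p`; for `p = 3` the printed two-decimal renderings of the edges
are 1.67 and 2.33. Brackets are left-closed/right-open with the final
bracket closed, so 3.0 maps to the top category. The boundary behaviour
is measure-zero for continuous scores; the convention is documented
because a panel score of exactly 7/3 (e.g. a 10-rater mean) does occur.

## Training protocol and the desk reference configuration

The reference training protocol uses batches of 12 patches, a plateau
schedule at 30% decay, and 10-epoch patience for both decay and early
stopping. The full-scale configuration (`regressorConfig()`) keeps the
512-px / 0.5 µm-per-pixel patch geometry with 200 training and 500
validation iterations per epoch. All experiments in this package run the
**desk configuration** (`deskConfig()`): 64-px patches at 0.5 µm/pixel, a
stem of 12 channels pooled once, three dense blocks of two layers at
growth 8 with 0.5-compression transitions (about 9000 parameters), Adam at
1e-3, 100 training and 28 validation iterations per epoch, at most 25
epochs. The problem sizes of the reference experiment — 125 ROIs of
320 px in 39 slide-like groups, split 52/28/45 slide-wise, 58 training
patches per training ROI (roughly 3000) — were fixed once as a
desk-scale mirror of the ROI-study structure. Validation batches cycle
deterministically through a fixed pool, so the validation loss is
comparable across epochs; training batches resample with replacement
under the run seed. All computation is single-threaded and seeded, so
training runs are bit-reproducible.

Augmentation composes one of the 8 dihedral transforms, a
hematoxylin/eosin stain-space jitter (per-channel scale within ±15%,
offset ±0.03 OD — ranges that keep augmented images inside the valid
intensity range), and Gaussian blur with sigma drawn from [0, 1] px.
Input patches are normalized by fixed constants (mean 0.65, sd 0.25,
roughly centering the rendered tissue distribution).

## Grad-CAM for a regression output

Saliency uses gradient-weighted class activation mapping: channel-wise
gradients of the scalar output with respect to a dense block's feature
maps are global-average-pooled into weights, the weighted feature-map sum
is rectified, upsampled, and max-normalized. Two regression-specific
choices:

* **Direction.** Classification Grad-CAM differentiates the score of the
  class of interest. For a bidirectional severity score the analog is
  the predicted half of the spectrum: for predictions below the midpoint
  2 the map is computed for the score-*lowering* direction — the
  evidence that the nuclei look normal is on the nuclei, whereas the
  positive direction would highlight background ("nothing abnormal
  here"). `direction = "increase"` restores the classic behaviour.
* **Target layer.** The default targets the penultimate dense block,
  whose feature maps retain twice the spatial resolution of the last
  one; at 64-px input the last block's 8×8 maps are too coarse to
  separate nuclei from their surroundings.

A constant model has zero gradients everywhere; the map is returned
all-zero and flagged rather than normalized into noise.

## Slide inference details

Tile grids advance by `tileSize - overlap`; when the last stride does not
land on the image edge, one extra tile shifted to end exactly at the edge
is appended. This keeps every tile at full size (identical input
statistics for every prediction) at the cost of extra overlap near two
borders. Block pooling weights each covering tile by its rasterized
intersection area with the block — for the aligned default geometry the
weights are all 1 and the block score is the plain mean; the area weights
only matter for the shifted boundary tiles. Blocks no tile contributed
to are `NA`, never 0 (a 0 would be a valid-looking severity). The slide
score averages tumor-masked blocks only; `maskMode = "all"` reproduces
the failure mode in which low-scoring benign regions pull the slide score
down, which is useful for studying detector false positives.

## Numerical and degenerate-input choices

* Severity values are validated to [1, 3]; `quantize` refuses values
  outside (clamping is the caller's explicit decision).
* A region too small to hold a nucleus yields an empty record set with a
  typed warning, not an error — mosaic layouts legitimately contain
  slivers.
* An all-zero density map (no tumor detections) raises a typed
  `pleoNoTumorError`: a slide without detected tumor has no defined
  pleomorphism score, and fabricating one would be worse than failing.
* Smooth-L1 uses `beta = 1`, the canonical transition point; the loss is
  computed on the unclamped output so gradients never vanish outside
  [1, 3].
* "Decreased by 30%" is implemented as `lr <- 0.7 * lr` (the rival
  reading, "decayed *to* 30%", would cut the rate by 70% per plateau and
  is rejected as implausibly aggressive).
* Both plateau counters reset on improvement; the decay counter also
  resets after a decay, so repeated plateaus decay repeatedly while a
  single stagnation window of 10 epochs triggers decay and stop in the
  same epoch.

## Known limitations

* The severity-to-morphology map is a modeling stand-in. Real
  pleomorphism involves nucleoli, chromatin clearing, membrane
  irregularity and mitotic context that the generator does not render;
  nothing here calibrates the synthetic severity scale to clinical
  scores.
* The blob detector is a desk-scale stand-in with the same output
  contract as a detection network, adequate on synthetic rasters (pooled
  recall ≈ 0.88 at a 10-px radius) but not a competitive nucleus
  detector for real H&E.
* The desk regressor's accuracy figures (patch MAE ≈ 0.18 against the
  generating severity, Spearman ≈ 0.94 on held-out patches, ROI-level
  quadratic kappa ≈ 0.89 against quantized truth, 12/12 homogeneous
  slides recovered) are produced by `scripts/acceptance.R` and the test
  suite on synthetic data; they say nothing about clinical performance.
* Single-patient multi-slide aggregation, pyramidal WSI containers and
  stain normalization at inference are out of scope.
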