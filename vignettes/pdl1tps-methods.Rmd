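---
title: "Methods: TPS-assisted PD-L1 scoring with pdl1tps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TPS-assisted PD-L1 scoring with pdl1tps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

PD-L1 expression in non-small cell lung cancer is reported as the Tumour
Proportion Score,

$$\mathrm{TPS}\% = \frac{\text{number of PD-L1-positive intact tumour
cells}}{\text{total number of intact tumour cells}} \times 100,$$

with three clinical reporting categories: negative (< 1%), low expression
(1–49%) and high expression (≥ 50%). Inter- and intra-pathologist
variation concentrates near the two cut-offs, so an assistive pipeline is
most useful when it scores the easy middle of the range automatically and
routes scores near 1% and 50% to the reporting pathologist. `pdl1tps`
implements that pipeline end to end: segmentation of stained tissue into
background / positive tumour cell / negative tumour cell, connected-
component cell counting, tiled region-of-interest (ROI) scoring, and
interval routing — plus a seeded synthetic-data module that provides
ground truth for testing every stage.

## The segmentation model

`build_model()` constructs a U-Net-style encoder–decoder over
`H x W x 3` RGB rasters (H and W divisible by 32; other sizes are
rejected rather than silently padded so mask/image correspondence stays
exact). The default ("full") encoder follows the ResNet-34 pattern: a
7×7 stride-2 stem producing 64 feature maps, residual stages of
(3, 4, 6, 3) blocks at widths (64, 128, 256, 512), and a bottleneck
emitting 1024 feature maps at 1/32 resolution (8×8 for a 256×256
input). The decoder upsamples with 2×2 stride-2 transpose convolutions,
concatenating a skip connection from the encoder output at each
resolution, and ends in a three-class softmax head.

Two deliberate departures from the textbook recipe:

* **No batch normalisation.** Residual blocks use plain convolution +
  ReLU with identity (or 1×1 projection) shortcuts. At the batch sizes
  and network depths used here BN adds stochastic coupling between
  samples without measurable benefit, and omitting it makes training
  bit-reproducible on a single CPU — a property the test suite checks
  end to end.
* **Explicit thresholded prediction.** The head is a softmax over the
  three classes; `predict_mask()` assigns a pixel the foreground class
  with the larger probability *only if* that probability reaches
  `mask_threshold` (default 0.5), else background. Ties between the two
  foreground classes break toward the positive class, deterministically.
  With a three-way softmax a 0.5 foreground acceptance threshold is
  conservative: a pixel whose evidence is split between the two
  foreground classes can fall back to background even when foreground
  in aggregate dominates. Trained models on high-contrast data are
  confident enough that this is immaterial, and the threshold is
  config-exposed.

The engine underneath is an im2col formulation: convolutions,
transpose convolutions and the 3×3/2 max-pool are evaluated as BLAS
matrix products with exact hand-derived backward passes (verified
against finite differences during development). This keeps the package
dependency-free for training, deterministic, and fast enough for the
desk-scale sizes below.

### Reduced-depth variant

A `"reduced"` variant (selected via `build_model(..., "reduced")`) is
provided for CPU-scale experiments: stages halved (two residual stages
at widths 16 and 32), base width 16, bottleneck 64, and a stem that
keeps the 7×7 kernel but runs at **stride 1**. The stride-1 stem is the
one structural change relative to a shrunken ResNet: at desk scale the
patches are 64×64 px and cells only 6–14 px across, and with the short
training schedule the class-discriminating colour signal does not
survive an immediate 2× downsampling. The full variant keeps the
stride-2/pooling stem of its reference pattern.

### Training

`train()` runs seeded mini-batch Adam on the weighted cross-entropy
(WCE) loss

$$L = \frac{1}{N}\sum_{i} w_{t_i}\,(-\log p_{i,t_i}),$$

with class weights (0.4, 0.9, 0.9) for background/positive/negative by
default — background pixels dominate any stained-tissue patch, and the
weighting keeps the two cell classes from being drowned out.
Probabilities are clamped at 1e-12 so the loss is always finite.
Augmentation applies the same geometric transform to image and mask:
horizontal/vertical flips each with probability 0.5 and rotation
uniform in ±30°; the image is resampled bilinearly, the mask by nearest
neighbour so labels stay in {0, 1, 2}.

Defaults in `training_config()` follow the production settings
(learning rate 1e-4, 100 epochs, mini-batch 8, inputs normalised from
0–255 to [0, 1]). For desk-scale runs the package uses a short
schedule: 5 epochs at learning rate 2e-3 with mini-batches of 4. The
short-schedule values were set during development because 1e-4 over the
~10^2 optimizer steps a 5-epoch run affords leaves the network
essentially at its initialisation; they are deliberate package choices,
config-exposed, and recorded here rather than hidden in scripts.
(Note the mini-batch default of 8 follows the training description;
a batch of 16 also appears in the source hyperparameter table — the
field is configurable.)

## Counting cells

`label_cells()` turns a mask into cell objects: the binary mask of one
class is dilated with a box structuring element of radius 4 px (the
radius-4 neighbourhood of the connected-components search), the dilated
mask is labelled with 4-connectivity, and each original pixel takes the
label of its dilated component. Fragments of one cell that sit within
the merge radius therefore count once. Chebyshev (box) dilation is used
because it is the natural raster dilation; the radius and the base
connectivity are config-exposed. Dilation and labelling go through
EBImage; an independent brute-force flood-fill oracle in the test suite
checks exact agreement on random masks.

`count_cells()` accepts a `min_area_px` gate (default 0): an intact
tumour cell has a minimum plausible footprint, and without a gate a
single misclassified pixel becomes a counted "cell" in the TPS
denominator. The desk-scale scoring path uses 8 px — about half the
area of the smallest cell the synthetic generator can draw (major
radius 3 px, minor 1.5 px, ≈ 14 px) — so genuine cells are never
dropped, while sub-cellular prediction specks are. On real data the
gate should be set from the imaging resolution and expected nuclear
size.

`compute_tps()` raises a typed error (`pdl1_no_tumour_error`) on an
empty tally rather than emitting 0/0: a case with no detected intact
tumour cells must be reported as "no viable tumour", never as a score.

## ROI tiling

`tile_roi()` lays a row-major grid of `tile_px` tiles (default 256)
over the bounding box of the ROI polygon(s); pixels outside the polygon
or beyond the image are marked invalid and excluded from counting, and
partial edge tiles are padded with the pad marked invalid. Polygon
membership is tested at pixel centres ((col + 0.5, row + 0.5) in
0-based y-down pixel coordinates, the QuPath GeoJSON convention).
`score_roi()` segments each tile, counts per tile, sums the tallies and
computes the TPS on the sum, retaining per-tile tallies for audit. A
cell straddling a tile boundary is counted once per tile — faithful to
per-patch summation, and the known double-count risk is why the
generator offers `forbid_tile_straddle`, which confines every cell to a
tile interior so tiling-additivity tests are exact.

## Evaluation levels

* **Pixel**: 3×3 confusion matrix; accuracy; one-vs-rest sensitivity
  and specificity per class. A class absent from the ground truth has
  undefined sensitivity (reported `NA`, excluded from the macro mean).
  The macro figures average the two foreground classes, since
  background dominates and would mask cell-level performance; per-class
  values are always emitted alongside.
* **Object**: cells extracted with `label_cells()` from both masks;
  predicted and true objects match one-to-one, greedily by descending
  pixel overlap (ties toward the smaller object index), any positive
  overlap qualifying by default with an optional IoU threshold.
  Degenerate cases follow explicit conventions (empty vs empty is
  perfect; an empty prediction against a non-empty truth scores 0 and
  is flagged).
* **Patient**: Pearson correlation of paired case scores (Spearman also
  emitted), and interval concordance — the fraction of cases whose
  predicted interval equals the true one, under either the clinical
  three-category scheme or the routing bands.

## Interval routing

`default_scheme()` partitions [0, 100] into five half-open bands
[0, 1), [1, 5), [5, 40), [40, 60), [60, 100]: confident-negative,
unconfident-low, confident-mid, unconfident-high, confident-positive.
Scores in the two unconfident bands require manual scoring by the
reporting pathologist; the rest are auto-reported pending confirmation.
The upper review edge appears in the source material variously as 59.9,
59.99 and 60; the package uses 60 as the exclusive edge (configurable),
and likewise resolves the low band's upper edge to 5. The
unconfident-high band deliberately straddles the clinical 50% cut-off:
the band determines *review*, while the clinical category is always
derived from the final score with cut-offs at 1 and 50. `route_case()`
refuses to finalise an unconfident case without a pathologist score and
records provenance (algorithm / pathologist-confirmed /
pathologist-overridden).

## The synthetic-data module

Real PD-L1 slides and the trained production weights are not
distributable, so the generator provides the controlled ground truth
the tests run on. Each patch is a pale eosin-pink background with
additive Gaussian noise (sd 0.02) on which non-overlapping ellipses are
placed by seeded rejection sampling (1000 attempts per object, then a
typed packing error — never silent truncation):

* **positive tumour cells**: DAB-brown discs with a darker rim
  (membranous-staining hint), labelled 1;
* **negative tumour cells**: haematoxylin-blue discs, labelled 2;
* **distractors**: smaller (2–3 px radius), paler brown-tan blobs
  mimicking PD-L1-bearing macrophages "hugging" tumour clusters —
  rendered with a positive-like stain but labelled background, so a
  correct model must learn to ignore them.

Cell eccentricity is ≤ 2 with random orientation; stain intensity and
per-cell brightness jitter are parameters. A master seed expands into
per-patch substreams, so identical (spec, seed) pairs are bit-identical.
`min_cell_gap_px` above twice the merge radius guarantees that
generated cells never fuse during counting, which closes the loop:
`count_cells()` on a generated mask returns exactly the generator's
tally, and a case's true TPS is exactly the ratio of its construction
counts.

Cohorts draw case counts per clinical category by rounding cumulative
proportions (default 0.30 / 0.35 / 0.35 for < 1% / 1–49% / ≥ 50%,
a typical NSCLC PD-L1 prevalence mix; the source cohort's exact
distribution is not published, so this is a package default, not a
reproduced value). Within a category the positive-cell count is drawn
uniformly from the compatible range and spread evenly over the case's
patches (four per case by default). The occasional infeasible packing
draw is retried from the seeded stream with the requested counts
unchanged.

What the generator does *not* emulate: tissue texture and nuclear
chromatin, stain variation across scanners, touching/overlapping cells,
necrosis, and the full morphological ambiguity of real macrophage
hugging (synthetic distractors differ from tumour cells in both size
and shade). Passing the desk-scale study therefore demonstrates that
the pipeline's machinery — learning, counting, tiling, scoring,
routing — is correct and internally consistent; it does not certify
performance on clinical material.

## Desk-scale study sizes

The end-to-end study run by `run_synthetic_benchmark()` (and by
`scripts/acceptance.R`) uses: 200 training patches of 64×64 px (0–2
cells of each class and 0–1 distractors per patch, radius 3–4 px, gap
9 px), 5 epochs of the short schedule above, 40 held-out patches for
pixel accuracy, and 20 held-out four-patch cases (16 tumour cells and
4 distractors each) for TPS agreement. These sizes were chosen so the
whole study trains and evaluates in minutes on one CPU while leaving
each stage non-trivial; all of them are function arguments.

## Known limitations

* The full-variant model is architecture-complete and shape-tested but
  not trained at production scale here; no pretrained weights ship with
  the package (`pretrained_encoder` points at checkpoints instead).
* Cells straddling tile boundaries double-count by design (see ROI
  tiling); real-ROI scoring should prefer tile sizes large relative to
  cell diameters.
* The min-area gate and the stain palette are tuned to the synthetic
  regime; both need re-deriving for real slides.
* Scores are case-level; no subcellular (membrane vs cytoplasm)
  scoring is attempted.
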