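---
title: "Counting fluorescent cells in larval zebrafish plate scans: models and methods"
author: "larvacount"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting fluorescent cells in larval zebrafish plate scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

High-content screens place one anesthetized zebrafish larva per well of a
96-well plate and image every well as an RGB Z-stack, because larvae settle
at unpredictable heights and only one slice of each stack is usefully in
focus. With a transgenic reporter line such as *Tg(lyz:EGFP)*, neutrophils
carry a green fluorescent label, and the endpoint of a genetic or chemical
screen is simply the number of labeled cells per larva. Manual counting
does not scale to plates; `larvacount` implements the automated pipeline:

1. **Larva segmentation.** A small U-Net assigns each pixel a probability
   of belonging to the larva; masks restrict all later computation to the
   animal, so well walls, debris and reflections can never contribute.
2. **Best-focus selection.** Every slice of a well's Z-stack is scored by
   the variance of the Laplacian of the segmented region; the slice with
   the maximal score is kept. The Laplacian responds to fine structure,
   which defocus destroys, so the in-focus slice maximizes the score.
3. **Masked to-zero thresholding.** Inside a second, higher-resolution
   mask, green-channel pixels below an intensity threshold are set to
   zero while brighter pixels are kept unmodified. Keeping values (rather
   than binarizing) preserves the radial intensity profile of each cell.
4. **Difference-of-Gaussian blob counting.** Bright compact spots are
   local maxima of a DoG scale space; their count is the per-larva cell
   count. Per-well counts feed standard population statistics
   (Mann-Whitney U tests, standard errors, least-squares regression).

## The two-resolution protocol

Segmentation cost grows quadratically with working resolution, and the two
pipeline stages need different accuracy. Focus scoring only needs a rough
region, so frames are downsampled to 256 px for stage 1; counting needs the
mask to cover the whole animal (a missed tail loses cells), so stage 2
segments at 1024 px. Both models are trained separately, one per working
resolution, because a network's weights are calibrated to the scale of the
structures it saw.

Native frames are 3072 x 3072 x 3 at about 3 um/pixel; a full plate slice
composites to 24,576 x 36,864 (about 906 megapixels), and a 31-slice stack
at a 100 um step spans 3.1 mm of travel.

## Segmentation model and training protocol

The segmenter is a fully convolutional U-Net: `depth` resolution levels
(default 4) of two 3x3 ReLU convolutions each, 2x2 max pooling on the way
down, nearest-neighbor upsampling with skip concatenation on the way up,
and a 1x1 sigmoid head. Feature widths start at `baseChannels` (default
16) and double per level. Because no deep-learning framework is assumed,
the forward pass, backpropagation and the Adam optimizer are implemented
in compiled code inside the package; the test suite pins the gradients to
central finite differences.

Training follows a fixed protocol: soft Dice loss
\[
L = 1 - \frac{2\sum_i p_i t_i + \varepsilon}{\sum_i p_i + \sum_i t_i + \varepsilon},
\qquad \varepsilon = 1,
\]
Adam for 50 epochs, learning rate 5e-4 divided by ten at epochs 15 and 40,
batch size 4. Images are downsampled to the working resolution with
area/bilinear interpolation and scaled to [0, 1]; label masks use
nearest-neighbor interpolation so labels never bleed. Open details are
fixed as package policy: final-epoch weights are used (no
validation-selected checkpoint), probability maps binarize at 0.5, and
masks return to native resolution by nearest-neighbor upsampling, which
keeps them strictly binary.

Training labels come either from VGG Image Annotator polygon outlines
(`loadViaAnnotations()`, rasterized by an inclusive pixel-center rule: a
pixel is foreground iff its center is inside or on the polygon) or from
the simulator's exact masks (`annotationsFromTruth()`). The 60-image
study split of 30/13/17 is generalized to 50/22/28 percent when the set
size differs.

## Focus metric

`varianceOfLaplacian()` convolves the focus channel (green by default --
the fluorescence channel carries the sharp structure of interest; the
choice is exposed because nothing in the protocol fixes it) with the 3x3
kernel `[[0,1,0],[1,-4,1],[0,1,0]]` under replicate padding and returns
the population variance over mask pixels. Two invariances make it a clean
focus score and are tested as such: adding a constant changes nothing
(the kernel annihilates constants), and scaling intensities by *k* scales
the score by *k^2*. Slices whose mask covers less than 1% of the frame are treated as
fishless; a well with no scoring slice is discarded, which is how empty
wells leave the analysis. The 1% floor is set from geometry: the smallest
plausible larva silhouette (a non-lateral fish) covers about 7% of the
frame at any working resolution, so an order of magnitude below that
separates real animals from stray pixel activations a segmenter may emit
on background. Exact score ties resolve to the
lower slice index so results are reproducible.

## Counting parameters

Three parameters required calibration on real acquisitions and are the
ones a user may need to revisit when imaging conditions change:

* `intensityThreshold = 55` (8-bit): inside the larva only labeled cells
  exceed this value. Mesh well inserts (porous liners that allow medium
  exchange) brighten the background texture visible through the fish, so
  mesh mode lowers the default to 30.
* `blobMaxSigma = 5` px: matched to cell size so clusters split into
  multiple blobs rather than merging into one.
* `blobThreshold = 0.05`: minimum scale-space peak intensity. The image
  is divided by 255 before scale-space construction, so this value lives
  on the normalized scale -- consistent with it being far below any 8-bit
  intensity.

DoG internals are exposed with standard values: minimum sigma 1, ratio
1.6 between successive sigmas, response normalization by
$\sigma_i / (\sigma_{i+1} - \sigma_i)$ so peaks are comparable across
scales, and greedy overlap pruning that keeps the stronger of two
detections whose discs (radius $\sqrt{2}\sigma$) overlap by more than
half. Local maxima use a 26-neighborhood with ties admitted (pruning
resolves plateaus); the packaged detector is tested against a brute-force
scan of the same scale-space volume.

The to-zero boundary rule keeps values exactly equal to the threshold;
this makes thresholding idempotent and is asserted as such.

## The synthetic plate simulator

Real plate scans are large and not distributable, so the package ships a
generator whose output is statistically shaped like the real assay and
whose ground truth is exact. Each well renders as:

* a larva silhouette -- a rotated superellipse with a brighter yolk disc
  and a dark eye spot; non-lateral fish (drawn with probability 0.026, or
  0.317 in mesh mode, matching the orientation rates of square and mesh
  plates) are shorter and rounder. Anatomical realism is deliberately
  out of scope: segmentation needs shape and pose variety, not fish.
* green Gaussian spots of known centers and count, placed by rejection
  sampling inside the *eroded* fish mask (margin: max of 3 spot sigmas
  and 5% of the frame) honoring a minimum separation. If a target count
  does not fit, placement reduces it and the truth records what was
  rendered -- the truth always matches the image. At the default 256-px
  fixture scale the 20-px separation caps counts near eight; the range
  acts as a target, and group comparisons in the tests use ranges far
  enough apart to survive the cap.
* melanophores (autofluorescent pigment cells) as rare dim confounders.
  Their total green peak equals the configured amplitude (default 42):
  below the square-plate threshold 55, above the mesh threshold 30, which
  reproduces the real failure mode of one-to-three spurious counts at
  the lower threshold.
* defocus: slice *z* is the in-focus scene blurred with Gaussian sigma
  `defocusBlurPerSlice * |z - zTrue|` (computed incrementally via the
  Gaussian semigroup), plus i.i.d. Gaussian read noise per slice, then
  quantization to 8 bits. Blur increases strictly with distance from the
  true plane, which is the hook that makes focus selection testable.
* composition: exactly `round(fishProb * wells)` wells are occupied,
  drawn once per plate, so the canonical 87-of-96 plate is reproduced.
* randomness: one seed; per-well substreams derive from the well index,
  so results do not depend on generation order.

What the simulator does **not** model: optical point-spread functions,
photon shot noise, Bayer mosaics, camera vignetting, 3-D fish geometry,
or pigment spectra. Passing the recovery tests therefore demonstrates
that the pipeline's logic is correct and its parameters mutually
consistent -- not that the shipped fixture models segment real larvae;
real deployments train on real annotated frames via the VIA path.

## Fixture problem sizes

The packaged tests and the acceptance script run the full study at a
scaled geometry chosen to keep a complete run on one CPU in minutes:
synthetic frames are 256 px (native protocol / 12), the two-stage
protocol becomes 64-px focus segmentation with counting at 128 px, and
fixture networks use 8 base channels (4 at 1024 px). Counting on the
downsampled frame mirrors the native protocol (which counts at 1024 on
3072-px frames) and also averages out single-pixel read-noise excursions
at the threshold boundary. The segmentation training plate holds 24
single-slice wells, balanced roughly 60/40 between fish and background
wells -- background-only examples are what teach the network to emit
empty masks on empty wells. For the resolution-trend comparison the
64-px and 128-px models train for 40 epochs from random weights; the
1024-px model is trained by progressive refinement: starting from the
trained 128-px weights, resolution doubles stage by stage (256, 512,
1024 px) with two single-image-batch fine-tuning epochs per stage on a
fish-balanced training subset. The fully convolutional architecture
permits weight reuse across scales, each 2x jump keeps the learned
features within range of the new structure scale, and the whole chain
brings high-resolution training from hours to minutes. Optimization (re)starts ramp the learning rate over
the first five steps: Adam's bias-corrected early updates are full-size
sign steps before its moment estimates carry information, and without
the ramp a resumed run can destroy the initialization it started from.
Trend accuracy is compared on fish-containing test frames (IoU against
an empty truth mask collapses to zero on a single stray pixel, so empty
frames carry no gradation). The coarse model's accuracy is capped by its
4x nearest-neighbor upsampling to the native frame; the refined fine
model is past that ceiling, which is the trend the comparison
demonstrates.

## Statistics

Counts are compared with a Mann-Whitney U test (cell-count distributions
are not normal), `U = min(U_a, U_b)` with midranks. With no ties and a
combined sample of at most 12 the two-sided p-value is exact (the null
distribution is fully enumerable and the tests check it against explicit
enumeration); otherwise the normal approximation with tie-corrected
variance is used, without continuity correction so that identical samples
give p = 1. Group summaries report mean, standard error
(sd/sqrt(n), n-1 denominator) and the star convention (`*` p <= 0.05
through `****` p <= 1e-4); groups in which one side is all zeros are
reported but flagged untested, since a rank test against an all-zero
sample is degenerate. Pooled manual-vs-algorithmic agreement is an
ordinary least-squares regression with intercept (nothing justifies
forcing the origin) summarized by R^2 = 1 - SS_res/SS_tot. No
multiple-testing correction is applied; comparisons are reported
per group.

## Known limitations

* Counts are per best-focus slice, not per volume; cells stacked along
  the optical axis merge. The assay is a relative population measure.
* Orientation (lateral vs non-lateral) is accepted as a manual annotation
  column and never inferred; mesh-plate studies exclude non-lateral fish
  by filtering that column.
* The DoG detector reports centroids, not boundaries; touching cell pairs
  closer than the resolvable separation (about four spot sigmas) count
  as one.
* The HDF5 container stores one plate per file; multi-plate batches are
  out of scope.
* Fixture models are trained on synthetic scenes and are not usable on
  real images.
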