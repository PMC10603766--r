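---
title: "Methods: synthetic spheroid scenes, morphometrics and AP evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic spheroid scenes, morphometrics and AP evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheromorph)
```

## What this package models

Collagen gel contraction assays embed a multicellular spheroid in a
collagen droplet and follow the cell-driven shrinkage of that droplet over
time; the readout is the projected spheroid area in brightfield images,
typically acquired hourly over a 24-hour window. Analysing such assays
requires four computational pieces, all provided here:

1. **instance segmentation** of each spheroid (delegated to a pluggable
   detector backend),
2. **morphometrics** per instance — area, perimeter, circularity, masked
   mean intensity,
3. **evaluation** of a detector against manual polygon annotations with
   the standard instance-segmentation metrics (IoU, precision, recall,
   AP, AP@0.75, AP@[0.5:0.95]), and
4. **kinetics summaries** (normalized area over time, endpoint
   comparisons).

Because trained segmentation models and their source images are
licensing- and size-bound, the package is built to be fully testable
without them: a synthetic-scene generator produces images with *exact*
ground truth, and the detection layer accepts any backend that returns
`(mask, score)` pairs.

## Shared geometric conventions

All modules use one convention, chosen to remove the off-by-one
ambiguities that plague pixel geometry:

* coordinates are 0-based with x = column, y = row; the pixel stored at
  matrix cell `[r, c]` has its center at `(c - 1, r - 1)`;
* bounding boxes are half-open (`x_max`, `y_max` exclusive), so box area
  is a plain product and abutting boxes do not overlap;
* a pixel belongs to a polygon iff its **center** is inside under the
  even-odd rule; centers exactly on the boundary follow a top-left rule
  (scanline spans are half-open), so two polygons sharing an edge
  partition the pixels rather than double-claiming them.

The rasterizer is a scanline implementation of exactly that definition;
the test suite holds it to *exact* agreement with a brute-force
point-in-polygon oracle on random polygons.

`mask_to_polygon()` inverts rasterization: it traces the 0.5-level
isoline between inside and outside pixel centers of the largest connected
component (holes are filled first — spheroids are treated as filled
regions, and hollow ring-like structures are a documented failure mode of
learned detectors, not a supported geometry). A useful consequence,
exploited throughout the tests: re-rasterizing the traced contour
reproduces the hole-filled mask exactly, so contour-based measurements
and mask-based measurements agree.

## Morphometrics

* **Area** is the exact count of pixels inside the contour boundary.
* **Perimeter** is the Euclidean length of the closed contour polygon.
* **Circularity** is the ISO-style shape factor `4 * pi * A / P^2` (1 for
  a disk, lower for elongated shapes). No formula for circularity is
  universal in assay software; this choice is stated prominently because
  other tools sometimes use diameter-ratio definitions, and values are
  not comparable across definitions.
* **Mean intensity** follows the contour-fill procedure used by
  segmentation pipelines: build a zero image of identical shape, set all
  pixels inside the contour to 255, collect the coordinates of 255-valued
  pixels, and average the original image there. The intermediate 255
  image is exposed (`fill_contour_image()`) so tests can verify the
  procedure literally; the result equals the mean within the rasterized
  mask.

One numerical subtlety: the traced pixel-edge contour of a smooth shape
is a staircase, which inflates its length by roughly 2–5% relative to
the true boundary, biasing circularity of a disk visibly below 1.
`measure_instance()` therefore measures the perimeter on a lightly
smoothed copy of the contour (circular moving average, window 5 — small
enough to preserve genuine shape, large enough to cancel the staircase);
area and intensity always use the exact contour. With this choice a
rasterized disk of radius 50 measures circularity ≈ 0.99 and the value
drifts by well under 2% when the disk is scaled ×2.

## The synthetic scene generator

`render_spheroid_image()` emulates a brightfield well image: a light
background (default level 200) with an optional linear illumination
gradient, dark elliptical spheroids (default fill 80), optional small
dark debris blobs, and additive Gaussian noise clipped to [0, 255]
(default sigma 8 — visible grain that does not obscure a spheroid;
additive Gaussian is the simplest model reproducing brightfield camera
grain). Defaults are 256 × 256 8-bit frames; bit depth and scale carry no
special meaning and are free parameters.

Ground truth per spheroid is a 128-gon boundary polygon, its
rasterization as the instance mask, and the analytic ellipse area
`pi * a * b`. The 128-gon keeps the polygon area within 0.1% of the
analytic value; the mask is *defined* as the rasterization of the
polygon, so polygon and mask are exactly consistent, and the mask's
pixel count agrees with the analytic area to well within 2% for the
spheroid sizes the generator draws (semi-axes 15–40 px). Debris blobs
are deliberately excluded from ground truth so that false-positive
behavior of detectors can be exercised; hollow scenes render a ring but
keep the filled outline as truth, mirroring how annotators outline such
structures.

What the generator does **not** emulate: optical blur and shading beyond
a linear gradient, textured spheroid interiors, overlapping spheroids,
meniscus artifacts, or multichannel fluorescence. Tests passing on these
scenes therefore demonstrate correctness of the measurement and
evaluation machinery, not robustness of any detector to real assay
variability — that is precisely why the detection layer is pluggable.

Dataset assembly (`generate_dataset()`) assigns images to splits by
largest-remainder apportionment of `n * fractions`: integer parts first,
remaining images to the largest fractional remainders. This makes counts
sum exactly to `n` (a 70/30 split of 480 images gives 336/144); designs
that are not exact fractions, such as a 265/117/50 train/validation/test
partition of 432 images, are requested as explicit `split_counts`.

Contraction kinetics (`simulate_contraction_series()`) follow
`area(t) = A0 * exp(-rate * t)` with unit-mean multiplicative lognormal
noise of the requested coefficient of variation. Assay literature shows
no single canonical kinetic law; exponential decay is the simplest
strictly-positive monotone model, it makes log-linear rate recovery exact
at zero noise (a property the tests assert), and the noise model keeps
areas positive at any CV.

## Detection

`detect_spheroids()` is a contract, not a model: a backend maps an image
to raw `(mask, score)` pairs; the toolkit validates shapes and score
ranges, derives bounding boxes, filters at `score_threshold` (default
0.5 — detection convention; the threshold is the user's main lever
against debris-induced false positives) and orders instances
deterministically (descending score, then larger area, then top-left).
Raising the threshold can only shrink the result list — asserted as a
property test.

The bundled `baseline_threshold_detector()` is a classical pipeline:
global Otsu (or fixed) threshold, morphological opening (disc radius 1),
connected-component labeling, minimum-area filter (default 100 px, above
the generator's debris size), with the component's Weber contrast against
the background as a confidence score clamped to [0, 1]. Classical
thresholding famously does not transfer across heterogeneous real assay
conditions; the baseline exists so every downstream stage is testable on
controlled images, and as the reference backend in end-to-end tests. No
non-maximum suppression is applied: the evaluation's one-to-one matching
already penalizes duplicates as false positives.

## Evaluation

IoU is overlap over union, for masks (pixel sets) and boxes (half-open
interval arithmetic); IoU of anything with itself is exactly 1, and two
empty regions have undefined IoU (an error, never a silent 0).

Matching follows the COCO convention: within an image, predictions in
descending score order each claim the unmatched ground truth of highest
IoU, provided it reaches the threshold; duplicates become false
positives, unclaimed truths false negatives. Precision is TP/(TP+FP),
recall TP/(TP+FN). The dataset-wide PR curve ranks all predictions by
score (deterministic tie-breaks make AP invariant to permuting
equal-scored predictions), and AP integrates the curve with all-point
interpolation: precision is replaced by its running maximum from the
right, then summed over recall increments — the exact area under the
monotone envelope, with an optional 101-point sampled mode
(`method = "coco101"`) for cross-checking against COCO-style tooling.
`mean_ap()` evaluates AP at the ten IoU thresholds 0.50, 0.55, …, 0.95
and averages them (AP@[0.5:0.95]), also reporting AP@0.75. With a single
"spheroid" category, the class-mean mAP coincides with AP. maxDets
limits and area-range buckets are not applied.

The test suite pins this machinery to an independently written
brute-force reference (explicit greedy matching plus rank-by-rank
cumulative AP) on hundreds of random small scenes, to 1e-9.

## Pipeline and problem sizes

`cmd_predict()` maps an image directory to the results CSV (one row per
instance: `image_id, instance_id, area_px, perimeter_px, circularity,
mean_intensity, score`), logging per-image detection counts and listing
zero-detection images in a skip report rather than failing.
`cmd_visualize()` produces the standard contraction readouts — area
kinetics, area normalized to each replicate's first timepoint (100%),
endpoint distributions — plus a per-group summary CSV and, for exactly
two groups, a Wilcoxon rank-sum endpoint comparison (a deliberately
assumption-light default; it is a convenience statistic, not a
substitute for a model of the full time course). `runtime_benchmark()`
asserts the *property* that prediction time grows linearly in image
count (R² of a straight-line fit across an ≥8× size range), never a
wall-clock constant, so it is stable across hardware.

Test and example problem sizes are chosen for a laptop-class single
core: 256 × 256 scenes, datasets of 8–40 images, 200-scene evaluation
sweeps. All quantities asserted are size-independent definitions or
relative tolerances, so scaling up changes nothing but runtime.

## Known limitations

* The baseline detector assumes dark-on-light instances (a polarity flag
  exists) and fails on low-contrast or textured scenes by construction.
* Circularity values depend on the perimeter estimator; compare only
  within this package's definition.
* Hollow structures are measured over their filled outline — interior
  voids do not reduce area.
* VIA parsing accepts polygon, polyline, rect, circle and ellipse
  regions (curved shapes as 64-gons); COCO-JSON annotation ingestion is
  out of scope.
* Volume and cell-count estimation are out of scope; only 2D projected
  measurements are provided.
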