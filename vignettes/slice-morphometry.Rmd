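---
title: "Methods: calibrated slice morphometry and the lightweight detection blocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibrated slice morphometry and the lightweight detection blocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slicemetry)
```

## The measurement problem

Quality grading of herbal decoction slices (the motivating material is white
peony, *Paeoniae Radix Alba*) relies on the physical size of each slice: its
longest diameter, shortest diameter, and area. Measuring thousands of slices
with a caliper does not scale, but a photograph contains all the needed
geometry *if* the pixel-to-millimeter scale is known. The trick used here is
an in-frame reference object: a rectangular card of known physical size
(26 × 38 mm by default) lies in every image, and its pixel dimensions anchor
the scale

$$\mathrm{PPM} = \frac{W_{\mathrm{pixels}}}{W_{\mathrm{mm}}},$$

the pixels-per-millimeter ratio computed from the card's short side. Every
contour measurement in pixels then converts to millimeters by division.

## The measurement pipeline

`measure_image()` chains five stages, each exposed as its own function:

1. **Grayscale** (`to_grayscale`): BT.601 luminance, `0.299R + 0.587G +
   0.114B`, rounded to integers.
2. **Denoise** (`gaussian_blur`): separable normalized Gaussian, default
   5 × 5 with σ = 1 px, reflective (edge-repeating) border so total
   intensity is conserved.
3. **Edges** (`edge_map`): Canny — Sobel gradient magnitude, non-maximum
   suppression along the quantized gradient direction, dual-threshold
   hysteresis. A pixel whose gradient magnitude reaches the upper threshold
   is a strong edge; weaker responses survive only when 8-connected to a
   strong edge. The single-threshold gradient test ("edge if
   $\nabla I \ge T$") is exactly the strong-edge half of this rule; the
   hysteresis pair is what the dual-threshold description in the source
   method adds. Defaults `t_low = 50`, `t_high = 150` on 8-bit Sobel
   magnitudes are common Canny practice; the method's description states no
   values, so both are configuration.
4. **Contours** (`find_contours`): measurement needs closed polygons, and a
   raw Canny ring can carry one-pixel gaps. Contours are therefore taken
   from the *regions bounded by edges*: a 3 × 3 morphological closing seals
   gaps, interior holes are filled, connected regions are labeled, and each
   region's outer boundary is traced. Area is the shoelace area of that
   polygon.
5. **Calibration and measurement** (`find_reference`, `compute_ppm`,
   `measure_slice`): the card is identified purely by the aspect ratio of
   its minimum-area rotated rectangle (within 10% of 38/26; largest area
   wins among candidates, since the card is larger than any slice), never
   by intensity. PPM is the short rectangle side divided by 26 mm; the
   38-mm side is a consistency cross-check that warns beyond 3%
   disagreement and fails calibration beyond 10%. Each remaining contour
   becomes `long_mm`, `short_mm` (min-rect sides / PPM) and `area_mm2`
   (shoelace / PPM²); contours under `min_area_px = 400` px² are reported
   as filtered specks.

### Why the rotated rectangle

The source procedure mentions bounding-box width and height, but also calls
the outputs "minimum diameter and maximum diameter", which an axis-aligned
box does not deliver for rotated slices: its sides grow with rotation angle
and the measurement would not be rotation-invariant. The package therefore
uses the minimum-area *rotated* rectangle (rotating calipers over convex
hull edges) for the reported diameters, and also emits the axis-aligned
extents (`bbox_w_mm`, `bbox_h_mm`) so both readings are available. This is a
deliberate design choice where the original description is ambiguous.

### Error and accuracy reporting

`error_accuracy()` implements
$\mathrm{Error}\% = |P - A| / A \times 100$, $\mathrm{Acc}\% = 100 -
\mathrm{Error}\%$, with the error rounded half-up to one decimal before the
accuracy is derived — this matches how published comparison tables are
printed and makes `error + accuracy = 100` hold exactly. The bundled
benchmark table (`slice_benchmark()`, 17 slices with caliper and image
measurements) contains two printed accuracy cells that contradict their own
error cells (objects 4 and 16, long diameter); the package keeps the table
as printed, documents the inconsistency, and the recomputed values (94.4
and 99.1) are what the formula yields.

## The synthetic scene generator

No public image set accompanies the method, so validation uses rendered
scenes with exact ground truth (`scene_spec()`, `render_scene()`,
`sample_scene_spec()`). A scene emulates the controlled acquisition setup:

* uniform background (the original used plain black or green backplates;
  since the pipeline grayscales first, the generator exposes an intensity
  level rather than a color);
* bright quasi-elliptical slices, 10–30 mm across, at arbitrary rotations;
* exactly one 26 × 38 mm card, rendered at an intensity *distinct from the
  slices* so that aspect ratio — the mechanism under test — and not
  brightness must identify it;
* anti-aliased 1-px shape edges, so sub-pixel measurement error behaves
  realistically instead of staircase-exactly;
* additive Gaussian noise (σ = 3 by default, mild sensor noise for indoor
  imaging), clipped to [0, 255]; the seed makes re-rendering bit-identical.

`sample_scene_spec()` fixes the validation conditions: 3–6 slices placed on
a jittered grid whose pitch exceeds the largest slice (objects never
touch), calibration drawn from 10–12.5 px/mm, noise σ from 1–5. The
contrast floor (≥ 60 intensity levels above background) guarantees the
Sobel response at object boundaries clears the default upper threshold.

What the generator does **not** emulate — and what passing its tests
therefore cannot show — includes real slice texture, surface cracks and
defects, uneven illumination, shadows, perspective distortion, touching or
overlapping slices, and camera optics. The recovery numbers on synthetic
scenes (diameter error well under 2% in the test suite) are a correctness
check of the geometry chain, not a field-accuracy claim.

## The neural building blocks

The second half of the package implements, from scratch and in plain
arithmetic, the blocks of a lightweight shared detection head, so that each
published structural claim is testable in isolation.

### Difference convolutions and reparameterization

`kernel_bank()` holds five parallel k × k branches: vanilla, center-,
horizontal-, vertical- and adaptive-difference convolution. Every
difference form is linear in the input, so each collapses to an ordinary
convolution with a transformed kernel (`transform_kernel()`), and the five
transformed kernels *sum* into one equivalent kernel (`merge_kernels()`):
convolving once with the merged kernel equals summing the five branch
outputs. `deconv_forward()` exposes both routes (`"parallel"` and
`"merged"`) and the test suite checks their agreement across 50 seeded
configurations — that equivalence is the reparameterization claim itself.

The center-difference transform is fully determined
(`w'(center) = w(center) − Σw`). The horizontal/vertical/adaptive forms are
inherited from the cited convolution lineage and not restated in the source
method, so the package fixes them explicitly and isolates them behind
`transform_kernel()` so they can be swapped:

* **hd/vd**: each tap minus its cyclic horizontal/vertical neighbor within
  the kernel window — shape-preserving, with zero row/column sums (a pure
  gradient response along that axis);
* **ad**: $\sum_p w(p)\,(F(p) - \sum_q a(q) F(q))$ with a learnable
  reference pattern $a$, initialized one-hot at the center, which makes the
  adaptive branch exactly the center difference at initialization.

### Fine-grained channel attention

`fca_weights()` follows the published formula chain: global average pooling
to a channel vector $U$; a local view from a width-k 1-D convolution across
channels (k = 3, circular padding — the minimal local-context choice, the
source states no width); a global view from a learnable per-channel
diagonal scaling; their outer product $M = U_{gc} U_{lc}^T$; and a fused
weight
$W = \sigma(\sigma(\theta)\,\sigma(U_{wgc}) + (1-\sigma(\theta))\,\sigma(U_{wlc}))$.
The symbols $U_{wgc}$/$U_{wlc}$ have no published definition; the package
reads them as the row means and column means of $M$, so each fuses one
branch's view of the cross-correlation. This is a documented
interpretation, not a published statement. Consequences verified in tests:
weights are strictly inside (0, 1); identical channels with a uniform
diagonal give equal weights; θ → ±∞ collapses to a single branch; θ = 0 is
the exact midpoint.

### Shared head, group normalization, box decoding

`lsd_head_forward()` runs, per pyramid level (strides 8/16/32): a per-level
1 × 1 channel reduction (hidden width 64 by default — the source is silent;
SiLU nonlinearity, the YOLO-family convention), then a *single shared*
detail-enhancing convolution with group normalization (8 groups) and single
shared 1 × 1 classification and regression layers, with a learnable
per-level scalar on the regression output compensating stride differences.
Sharing is why the head is light: `head_n_params()` counts the shared
configuration strictly below an equivalent per-level-copies head, and the
swap test (two levels exchanged, outputs exchange) proves the sharing is
real rather than per-level clones.

`dfl_decode()` implements distribution-based box regression: each box side
is a softmax distribution over `reg_max = 16` bins, the decoded distance is
its expectation times the level stride, and sides are offsets from cell
centers, clamped so `x2 ≥ x1`, `y2 ≥ y1`. Channel layout is
per-side-contiguous bins (l, t, r, b). A standard greedy NMS
(`nms_boxes()`, IoU 0.45, ties by insertion order) exists only so the
pipeline can emit discrete detections; no training, assignment, or loss
code is in scope.

Because the backbone/neck that would feed the head is out of scope,
`run_pipeline()`'s optional detection path builds a deterministic
image-pyramid stub (`image_pyramid_features()`): average-pooled grayscale
projected to the required channel counts. It exercises shapes and decoding
end-to-end; it carries no learned semantics.

### Detection metrics

`match_detections()` uses score-descending greedy matching per image and
class at a fixed IoU threshold (each ground truth matched once; IoU ties go
to the lowest ground-truth index); `precision_recall()` defines 0/0 as 0;
`average_precision()` integrates the all-point interpolated
precision–recall curve (the modern evaluator convention — the source does
not name its interpolation), and `detection_metrics()` averages per-class
AP into mAP, excluding (with a warning) classes that have predictions but
no ground truths.

## Numerical choices and degenerate inputs

* Coordinates are 1-based `(row, col)` with pixel centers at half-integer
  physical positions; all reported geometry (extents, rect sides, areas) is
  origin-independent.
* Non-maximum suppression breaks two-pixel plateau ties asymmetrically
  (≥ toward the positive gradient direction, > toward the negative), so an
  ideal step yields a one-pixel line.
* Hysteresis connectivity is 8-connected via a sparse union-find over edge
  pixels; region labeling of filled objects is 4-connected, which is
  sufficient for solid regions.
* `min_area_rect` needs ≥ 3 non-collinear points; anything less is a
  degenerate-contour error. Empty edge masks yield empty contour lists, not
  errors.
* Report rounding is half-up at one decimal; accuracies are derived from
  the rounded error so the 100% identity is exact.
* The variance floor in `group_norm` is `eps = 1e-5`; a constant group maps
  to exactly zero.

## Problem sizes

The shipped validation uses 20 sampled scenes (≈ 1200 × 1300 px) for the
measurement-recovery study, 50 seeded configurations for the
reparameterization equivalence, and small tensors (≤ 2 × 6 × 14 × 14) for
the block-level oracles; these sizes give stable statistics while keeping
the default test run fast. `scripts/acceptance.R` recomputes the same
quantities from scratch under a caller-supplied seed.

## Known limitations

* Exactly one reference card per image; multi-card scenes and perspective
  correction are out of scope.
* Touching slices are measured as one object (no watershed splitting).
* The published trained-model detection results are not reproducible
  without the original image set and training; only the structural claims
  of the blocks, the metric conventions, and the published arithmetic are
  validated here.
* Grade assignment from diameters is not implemented: the grading standards
  are not specified numerically in the source method.
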