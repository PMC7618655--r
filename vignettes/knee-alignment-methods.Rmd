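---
title: "Automated knee-alignment measurement: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated knee-alignment measurement: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Varus/valgus knee alignment on an anteroposterior (AP) radiograph is
summarised by the anatomical tibiofemoral angle (aTFA): the angle between
the anatomical femoral shaft axis and the tibial shaft axis, reported as a
signed deviation from straight alignment — valgus (lateral deviation of the
distal tibia) positive, varus negative. Manual measurement is slow and
requires consistent axis construction, so this package automates the chain

1. localize anatomical landmarks outlining the distal femur and proximal
   tibia,
2. derive shaft axes from named landmark subsets,
3. report the signed angle, plus localization-error and method-agreement
   statistics.

Because clinical radiographs and their annotations are not redistributable,
the package ships a synthetic left-knee phantom generator with exact
landmark ground truth; every claim a test makes is made against that
generator.

## Landmark localization model

Localization is heatmap regression with a single **hourglass**
encoder–decoder per search stage. Skip connections pass through **additive
attention gates**: the skip feature `x` and the coarser decoder feature `g`
are projected by 1×1 convolutions, summed, rectified, projected to a scalar
field, squashed by a sigmoid and used to gate `x` spatially. The gate output
therefore lies in (0,1) and gated features are never larger than ungated
ones — both properties are asserted in the tests.

Two stages share this architecture:

* **global search** (default: depth 4, width 8, 64 px input) scans the whole
  image for two reference points — the tibial plateau corners;
* **local search** (default: depth 4, width 16, 128 px input) localizes the
  full landmark set inside a similarity reference frame whose position,
  orientation and scale are fixed by those two points.

The reference regime for this architecture family is much larger (widths
32/256, hundreds of epochs on GPUs); the desk-scale defaults here are chosen
so that both stages train in minutes on one CPU. They are configuration, not
architecture: `model_config()` exposes depth, width, input size, heatmap
stride and the soft-argmax temperature.

### Heatmaps, decoding and the loss

Targets and decodes use a heatmap grid at 1/4 of the input resolution
(`heatmap_stride = 4`). Decoding is a spatial soft-argmax: the map is passed
through `softmax(beta * map)` and the expected (x, y) is taken, giving
sub-pixel coordinates and exact gradients. Training minimises the **wing
loss** on those decoded coordinates: logarithmic for residuals below `w`,
linear above, with the continuity constant `C = w - w*log(1 + w/epsilon)`.
The loss being a *coordinate* loss is the only coherent reading of combining
heatmap regression with a wing loss; `w = 10`, `epsilon = 2` px are the wing
defaults from the loss's original formulation, exposed in `wing_params()`.

Numerical choices worth recording:

* **Soft-argmax temperature** `beta = 25`. The encode→decode round trip at
  `sigma = 1.5` must stay within 0.5 px; a low temperature lets the uniform
  background mass drag the expectation toward the map centre (at `beta = 10`
  the bias is already several pixels on a 64×64 map), while `beta = 25`
  reduces the background mass to ~1e-7. The same temperature is used in
  training.
* **Near-zero output head**. The last 1×1 convolution is initialised at 2%
  of its He scale. With unit-scale initial maps, `softmax(25 * map)` is
  already saturated at a random pixel and gradients vanish; starting near
  the uniform distribution (decode = map centre) makes the coordinate loss
  trainable. This single choice moved desk-scale corner error from ~6 px to
  ~1 px in the 64 px frame.
* **Optimisation**: Adam. The reference learning rate is 1e-4; desk-scale
  runs take two orders of magnitude fewer steps, so the training helpers
  default to 2e-3 with a step decay (×0.25 at 60% of epochs) that sharpens
  final localization. A run is deterministic given its seed.
* **All-constant maps** decode to the map centre (softmax of a constant is
  uniform) with a warning rather than an error: an untrained model must
  still produce finite output.

### The reference frame

`make_frame()` returns the unique reflection-free similarity mapping the
two detected plateau corners onto canonical anchor positions in the crop.
Anchors sit at mid-height, separated by **0.17 of the crop width**. The knee
outline spans roughly five plateau widths proximodistally, so the crop must
zoom out this far to contain every landmark; the first implementation used a
half-width separation and silently cropped away every shaft landmark — the
local model cannot learn points it cannot see (nor represent coordinates
outside its map). Out-of-frame resampling fills with the image minimum so
the padded border stays radiograph-dark and attracts no heatmap mass.

During local-stage training the frame is built from ground-truth corners
jittered by 2 px (Gaussian, seeded) to emulate global-stage error. Larger
jitter occasionally pushes extreme landmarks outside the crop, which the
bounded soft-argmax cannot reach; 2 px matches the observed accuracy of the
trained global stage (~1 px in its 64 px frame ≈ 4 px in a 256 px image).

## Angle measurement

Two axis recipes operate on role-named landmark midpoints:

* **FTS** — femoral axis through the proximal/distal femoral shaft-pair
  midpoints; tibial axis through the proximal/distal tibial shaft-pair
  midpoints.
* **FNTS** — identical tibial axis; the femoral axis instead joins the
  proximal shaft-pair midpoint to the femoral intercondylar notch-pair
  midpoint.

The signed angle is measured between the distal prolongation of the femoral
axis and the tibial direction, `atan2`-based (equivalent to the arccos of
the clipped dot product in magnitude, but stable near zero), with the sign
mapped so that lateral deviation is positive for a left knee in AP image
orientation. Right knees are mirrored first (`flip_to_left()`); laterality
is metadata, never inferred from pixels. The measure is exactly invariant
under similarity transforms of the landmarks and exactly antisymmetric under
horizontal mirroring — both are acceptance properties.

## The synthetic phantom

`generate_phantom()` renders two bright bone-like polygons over a dark
background: a femur with condylar flare and a notch indentation, a tibia
with a flat plateau, blurred (Gaussian, sd 1.2 px) and noised (additive
Gaussian, sd 4 gray-levels of 255). Forty landmarks lie exactly on the
outlines; shaft pairs are symmetric about their bone axis, and the notch
midpoint lies on the femoral shaft axis, so FTS and FNTS share one
generating truth and both recover `true_atfa` to float precision. The
plateau-corner separation equals the configured tibial width, making the
evaluation reference length a generator contract.

Dataset draws are uniform over: aTFA ±15°, pose rotation ±10°, joint centre
±12 px around the image centre, shaft length 94–106 px, femoral width 36–44
px, tibial width 40–46 px (at 256 px image size; spatial ranges scale with
image size). These are the package's stated world: wide enough that the
localizer must actually generalise over pose/size/angle, narrow enough that
every draw keeps all landmarks in frame and satisfies
`shaft_length > 2*max(width)`.

What the phantom does **not** emulate: cortical/trabecular texture, soft
tissue, osteophytes or joint-space pathology, exposure variation, bilateral
fields, right knees (generation is left-only; the flip path is exercised in
tests), and the 134/181-point clinical annotation protocols (the schema is
role-complete but reduced). A green end-to-end test therefore establishes
that the pipeline machinery — training, frame algebra, decoding, measurement,
statistics — is correct and trainable; it does not establish clinical
accuracy.

## Evaluation and agreement

Localization: per-image mean point-to-point (P2P) and point-to-curve (P2C)
distances, the latter as clamped projections onto the ground-truth outline
polyline of the point's *own* bone (using the union would let errors hide
against the other bone's contour). Both are expressed as percentages of the
plateau-corner separation; summaries are mean/median/95th percentile with
type-7 (linear-interpolation) percentiles, a convention that must be named
because "95%ile" is ambiguous.

Agreement between paired angle series: **ICC(2,1)** (two-way random effects,
absolute agreement, single measure — the standard variant for method
comparison when bias is reported separately), with the F-distribution /
Satterthwaite 95% CI; **MAD** (mean absolute difference, SD with n−1); and
**Bland–Altman** bias ± 1.96·SD limits. Zero-variance input yields a flagged
`NA` ICC rather than a number.

## Known limitations

* The hourglass is a from-scratch implementation (no deep-learning runtime
  exists in the target environment): single hourglass, one residual
  convolution per block, nearest-neighbour upsampling. It is deliberately
  minimal; reference-scale widths would train impractically slowly on one CPU.
* Desk-scale accuracy gates (median rP2P < 5%, aTFA MAD < 2°) are smoke
  gates for the artifact, not clinical claims.
* Image I/O is PGM-only (no PNG/DICOM reader in the environment);
  `read_image()` fails loudly on other dialects.
* Angles are measured in the 2-D image plane of an AP projection, as in
  standard radiographic practice; no out-of-plane correction is attempted.
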