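---
title: "Estimating broiler body weight from top-view depth images"
author: "broilerwt authors"
output: rmarkdown::html_vignette
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Weighing broilers by hand is slow and stressful for the birds. A depth
camera mounted about a metre above the pen, looking straight down, offers a
contactless alternative: each bird appears as a valley in the
depth-distance image, and the shape and depth of that valley carry most of
the information a scale would give. `broilerwt` implements the full
estimation pipeline at desk scale:

1. **Instance segmentation.** Each bird gets a binary pixel mask. The
   package ships a deterministic depth-threshold segmenter (pixels more
   than `tau` mm above the ground plane, grouped into connected
   components) and a validation contract (`validate_segmentation()`,
   `segment_with()`) through which any external learned segmenter — in a
   production system, a Mask R-CNN — can be plugged in, provided it emits
   pairwise-disjoint masks of the image's shape.
2. **Morphometric features.** From each mask and its depth values, 25
   named features are extracted (`extract_features()`): contour area by
   the shoelace/Green's-formula integral, contour and hull perimeters,
   hull area, bounding-box width/height and area ratio, fitted-ellipse
   axes and eccentricity, Douglas–Peucker approximate-contour area and
   perimeter, convexity-defect maximum and sum, equivalent-circle
   diameter, approximate dome volume, and eight depth statistics.
3. **Feature fusion.** The 25 artificial features are concatenated with a
   2048-dimensional learned embedding into a 2073-vector (`fuse()`). The
   package does not train a CNN; it provides the embedding *contract*
   (`validate_embedding()`) plus a deterministic stand-in
   (`default_embed()`) built from pooled multi-scale patch statistics
   under a seeded random projection, so the fused pathway is exercised
   end to end.
4. **Weight regression.** A from-scratch gradient-boosted regression-tree
   estimator (`fit_gbdt()`): squared loss, residual fitting, mean-residual
   leaf values, shrinkage. Evaluation uses MAE, MSE, RMSE and R², plus a
   0.3 kg weight-class error breakdown.

Because the package is developed and tested without a real flock, a
synthetic-scene module (`generate_depth_scene()`) supplies ground truth:
birds are half-ellipsoid domes (semi-axes `a`, `b` px, height `h` mm) on a
flat ground plane at distance `H` mm, so every scene has closed-form
volumes, exact masks, and weights tied to volume through an allometric
model `w = c·V·(1 + eps)`.

## The boosting algorithm

With training set `(X, y)` the model is

```
f0(x)  = mean(y)
for k in 1..K:
  r_i  = y_i - f_{k-1}(x_i)            # negative gradient of 1/2 (y - f)^2
  T_k  = regression tree fitted to r on a row subsample
  f_k(x) = f_{k-1}(x) + rho * T_k(x)
```

Each tree is grown **leaf-wise** (best-first): among all current leaves,
split the one whose best split most reduces the squared error, where
candidate thresholds are midpoints of consecutive distinct sorted feature
values. Growth stops at `num_leaves`, at `max_depth`, or when no split
leaves `min_child_samples` rows in both children. Both caps are active at
once: the two common GBDT libraries cap leaves (leaf-wise growth) or depth
(level-wise growth) respectively, and honouring both reproduces either
regime by setting the other cap loose. Leaf values are mean residuals,
which is the argmin of the squared loss over a constant leaf — this
guarantees the training MSE is non-increasing in `K` whenever `subsample =
colsample = 1`, a property the test suite asserts over random datasets.

Numerical details that matter:

* **Tie-breaking.** Equal-gain splits resolve to the lowest feature index,
  then the lowest threshold; equal-gain leaves resolve to creation order.
  Fits are therefore bit-reproducible.
* **Phantom gains.** On a pure node the analytic gain is zero but floating
  point can produce ~1e-13 positives; a split must exceed a relative
  epsilon (`1e-11` of the parent score) to be accepted, so constant
  residuals yield a single leaf.
* **`min_child_weight`** is interpreted as a minimum leaf row count:
  under unweighted squared loss each row's hessian is 1, so the leaf
  hessian sum *is* its row count. This matches both library semantics for
  this loss.
* **Reseeding.** Round `k` draws its row/column subsample from a sampler
  seeded with `config$seed + k`, so any round is reproducible in
  isolation.
* The split scan is implemented in C++ (one pass over presorted feature
  orders per node) because an interpreted scan over 2073 columns is two
  orders of magnitude too slow to be usable; the algorithm is unchanged.

Presets: `gbdt_preset("lgbm-paper")` (4000 rounds, 15 leaves, depth 5,
`min_child_samples` 15, subsample 0.8) and `gbdt_preset("xgb-paper")`
(2000 rounds, depth 5, subsample 0.8, colsample 0.7) record the two
library configurations of the original experiments; `"desk"` (200 rounds)
is the default sized for synthetic-data work.

## Geometry conventions and their consequences

All modules share one coordinate convention: row-major images, origin at
the top left, pixel centers at integer coordinates, points as
`(x = column, y = row)`. "Counter-clockwise" is defined by the sign of the
shoelace integral.

**Contours** are traced on pixel centers (Moore neighbour tracing of the
largest component, collinear runs merged). A polygon through boundary
pixel *centers* encloses less area than the pixel region itself — about
half a pixel per boundary pixel, i.e. `perimeter/2`. This is documented
behaviour, not a bug: the projected-area feature f01 is the Green's
formula value, and its small systematic offset against the pixel count is
irrelevant to a regressor that only needs monotone shape information. Two
places where it *would* matter are handled explicitly:

* **Approximate volume (f17).** The volume of the valley is
  `base_area * reference_height - sum(masked depths)`. Both factors need
  care. The base area must be the *discrete* area of the summed region —
  the number of non-missing masked pixels `m` — because the subtraction
  pairs every base-area unit with one summed pixel; using the polygon area
  would leave `~perimeter/2` pixels unmatched, each contributing an error
  of a full reference height (~1 m), which swamps the signal. The
  reference height should be the camera-to-ground distance: the maximum
  depth over the contour's boundary pixels approximates it, but on
  rasterised footprints it falls short by an amount that depends on where
  pixel centers happen to land relative to the footprint edge, and this
  shortfall multiplies `m`. Measured on noiseless synthetic domes the
  contour-referenced volume errs by 1–10% (worst for pixel-aligned
  centers), while the ground-referenced volume stays within ~1%.
  `approximate_volume()` therefore defaults to the known
  `ground_distance` carried by every `depth_image`, with `"contour"` and
  `"mask"` reference modes available for images whose ground distance is
  unknown.
* **Scaling laws.** Doubling a footprint multiplies the polygon area by
  slightly more than 4 (the `perimeter/2` deficit does not scale
  quadratically); the effect falls below 2% once footprints exceed
  roughly 40 px semi-axes.

**Douglas–Peucker** simplification (`approx_contour()`) uses the standard
tolerance of 1% of the contour perimeter. The closed polygon is split at
the first vertex and the vertex farthest from it, and each open chain is
simplified recursively; `epsilon = 0` returns the input unchanged (no
free collinear elimination). Convexity defects are measured on the
approximate contour by default — the simplified polygon is what the defect
geometry describes — with `defects_on = "raw"` to switch.

**Ellipse fitting** uses second-order moments of the mask pixels: each
full axis is `4*sqrt(eigenvalue)` of the population covariance, which is
exact for ideal filled ellipses; eccentricity is the standard
`sqrt(1 - (b/a)^2)`. Width and height (f03/f04) are the axis-aligned
bounding-rectangle sides; the minimum-area rotated rectangle is computed
as a diagnostic but feeds no feature, since the feature list needs a
deterministic, orientation-stable definition.

**Depth statistics** use the population standard deviation (divide by
`n`); the masked depth values are a complete enumeration of the region,
not a sample.

## What the synthetic scenes emulate — and what they do not

`random_scene_spec()` draws a target weight from a truncated normal
(mean 1.599 kg, sd 0.277 kg, range 0.87–2.35 kg — the distribution of a
63-day-old bantam flock), converts it to a dome through the allometric
model (`weight_coef` 5e-6 kg per px²·mm; aspect ratio `a/b` uniform in
1.35–1.75; height-to-half-width `h/b` uniform in 2.2–3.0), and places
1–3 non-overlapping birds in the frame. The sensor model is additive
Gaussian depth noise (default 3 mm, truncated at ±3σ), a small fraction of
missing pixels encoded 0 (the usual invalid-value convention of 16-bit
depth streams), and quantisation to whole millimetres — the integer counts
a Z16 stream actually carries. Quantisation floors the in-bird pixels so
the noiseless mask/depth identity (mask = pixels strictly below ground
level) survives rounding, and it makes a written-and-reloaded scene
bit-identical to the in-memory one.

Deliberately **not** modelled: feathers and texture, head/wing/leg
articulation, posture variation, occlusion and contact between birds,
sensor-specific noise (edge dropout, multipath), and background clutter.
Consequently a passing recovery experiment demonstrates that the
geometry, feature and boosting code recover a known generative model
through the full pipeline — it does not certify field accuracy on real
flocks, where segmentation quality and posture outliers dominate the
error budget.

The half-ellipsoid dome was chosen over other "valley" shapes because it
admits a closed-form volume `(2/3)πabh`, giving every scene an analytic
oracle; its rim has infinite slope, which also stress-tests the
rasterisation-sensitive parts of the volume feature.

## Problem sizes and defaults

The recovery experiment (`run_recovery_experiment()`) defaults to 300
single-bird scenes of 180 × 240 px at 1000 mm camera height with 3 mm
depth noise, 3% relative weight noise, a grouped 70/30 split and a
200-round depth-5 GBDT; one run takes on the order of ten seconds. These
sizes were chosen so that the full suite exercises every stage at
meaningful sample sizes while staying comfortably interactive. The
noiseless variant used to check near-perfect recovery gives the trees
finer resolution (`min_child_samples = 1`, 400 rounds), since leaf
granularity is the dominant residual error once noise is absent.

## Known limitations

* The contour tracer assumes masks without 1-px-wide spurs (threshold
  segmentation with a minimum area, and dome footprints, guarantee this;
  arbitrary pathological masks may yield non-simple polygons).
* `mask_iou()` refuses two empty masks rather than defining 0/0.
* The embedding stand-in is a fixed random projection of patch statistics:
  deterministic and contract-complete, but not a learned representation;
  experiments that need genuine CNN features must plug in an external
  provider via `embed_with()`.
* Metric calibration (px to cm) is not attempted; 2D features are in
  pixels and the volume in px²·mm, matching a fixed-height camera setup
  where the regressor absorbs the constant scale.
* Weight-class MAE uses half-open bins with a closed last bin; weights
  outside 0.85–2.35 kg require `overflow = TRUE` (the recovery experiment
  enables it, since multiplicative weight noise can push a heavy bird
  past the top edge).
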