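# broilerwt

Contactless body-weight estimation for broiler chickens from top-view
depth images.

In a poultry house, a depth camera mounted about 1 m above the floor sees
each bird as a *valley* in the depth-distance image. `broilerwt`
implements the full estimation pipeline from such images to weight in kg,
plus a synthetic-scene simulator that makes every stage testable with
analytic ground truth:

* **Synthetic scenes** — birds as half-ellipsoid domes (closed-form volume
  `(2/3)πabh`) on a flat ground plane, with sensor noise, missing pixels,
  Z16 integer quantisation, and weights linked to volume through an
  allometric model `w = c·V·(1+ε)`.
* **Depth I/O** — 16-bit single-channel PNG (Z16 convention, 0 = missing)
  with lossless round trips, plus the classic piecewise-linear JET
  pseudo-colour rendering.
* **Segmentation** — a deterministic depth-threshold instance segmenter
  (connected components above `τ` mm over ground) and a contract
  (`segment_with()`) for plugging in external learned segmenters.
* **Morphometry** — the 25-feature artificial descriptor per instance:
  Green's-formula contour area, contour/hull perimeters and areas,
  bounding-box and hull area ratios, moment-ellipse axes and
  eccentricity, Douglas–Peucker approximate contour, convexity-defect sum
  and maximum (point-to-hull-edge distances), equivalent-circle diameter,
  approximate valley volume `m·H − Σ D_p`, and depth statistics.
* **Fusion** — concatenation with a 2048-dim learned-feature embedding
  (contract + deterministic stand-in) into a 2073-dim vector, with
  training-statistics min–max normalisation.
* **GBDT** — a from-scratch gradient-boosted regression-tree estimator:
  squared loss, residual fitting, leaf-wise growth with leaf *and* depth
  caps, shrinkage, row/column subsampling, bit-reproducible seeding.
* **Evaluation** — MAE / MSE / RMSE / R², 0.3 kg weight-class error
  breakdown, grouped train/test splits (all images of one animal stay on
  one side), and an end-to-end parameter-recovery experiment.

## Worked example

```r
library(broilerwt)

# two birds, 240 x 320 px, camera 1 m above ground, 3 mm depth noise
spec  <- random_scene_spec(seed = 7, n_birds = 2, rows = 240, cols = 320,
                           weight_sigma_rel = 0.03)
scene <- generate_depth_scene(spec)
print(scene$depth)
#> <depth_image> 240 x 320 px, ground 1000 mm, 0.2% missing, range [901, 1009] mm
scene$truth
#>   instance_id volume_mm3 weight_kg
#> 1           1   446438.3  2.208843
#> 2           2   313272.0  1.637968

masks <- threshold_segment(scene$depth)        # 2 instances found
feats <- extract_scene_features(scene$depth, masks)
round(feats[, c("f01_projected_area", "f07_major_axis_length",
                "f17_approx_volume", "f20_mean_depth")], 2)
#>   f01_projected_area f07_major_axis_length f17_approx_volume f20_mean_depth
#> 1             6369.0                107.58            432864         933.34
#> 2             5008.5                101.82            296864         942.15
```

The extracted volumes sit within ~3% and ~5% of the analytic dome volumes
(the threshold segmenter trims the shallow footprint rim), and the mean
depths show bird 1 standing taller — heavier — than bird 2.

The end-to-end recovery experiment simulates 300 scenes, segments and
measures them, and trains the GBDT on a grouped 70/30 split:

```r
rep <- run_recovery_experiment(n_scenes = 300, seed = 1)
rep$metrics
#> MAE 0.044826 kg  MSE 0.002977  RMSE 0.054561 kg  R2 0.955595  (n = 90)
rep$mae_over_mean
#> [1] 0.0285
rep$weight_class
#>   bin_lo bin_hi  n    mae
#> 1   0.85   1.15  3 0.0327
#> 2   1.15   1.45 27 0.0386
#> 3   1.45   1.75 38 0.0440
#> 4   1.75   2.05 18 0.0531
#> 5   2.05   2.35  4 0.0670
```

A test MAE of ~0.045 kg on a 1.6 kg mean weight (2.9% relative) against a
3% injected weight-noise floor means the pipeline recovers the generating
allometric model almost to the noise limit; R² = 0.956 on held-out birds.

A thin command-line front end wraps the same functions
(`inst/cli/broilerwt.R`): `simulate`, `segment`, `extract` (with
`--fuse yes` for 2073-dim vectors), `train`, `predict`, `evaluate`,
`recover`.

## Documentation

The methods vignette (`vignettes/depth-weight-pipeline.Rmd`) documents
the model, the geometry conventions (pixel-center contours and their
consequences for the volume feature), the boosting algorithm and its
numerical guards, what the synthetic scenes do and do not emulate, and
the package's known limitations.
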