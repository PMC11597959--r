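# pluckvision

Vision geometry for selective robotic harvesting of edible flowers
(marigold, snapdragon, pansy) from RGB-D frames.

A harvesting robot must cut each ripe flower's stem just below the
calyx. The cut point itself is invisible — hidden by the corolla and
leaves — so it has to be *inferred*. Given a colour image, the organized
point cloud registered to it (one 3D point per pixel, NaN for invalid
depth), and per-flower bounding boxes and segmentation masks from any
upstream detector/segmenter, `pluckvision` computes for each flower:

- **pose** — principal component analysis of the mask-isolated 3D
  points; for a disk-like corolla the minimum-variance eigenvector is
  the surface normal, i.e. the direction the stem extends (the *main
  axis*, sign-fixed to point away from the downward-looking camera);
- **diameter** *d* — project the points onto the plane orthogonal to
  the main axis, take the convex hull, and report the maximum pairwise
  hull-vertex distance (caliper width), in mm;
- **centre** — the Chebyshev centre (maximum inscribed circle, solved
  as a linear program over the hull's edge half-planes) of the mask
  polygon, placed in 3D on that pixel's viewing ray at the
  top-of-flower depth (mean of the top decile of points along the main
  axis);
- **plucking point** — predict the total height *h* (corolla top down
  to the cut) from the species' linear calibration, then translate:

  `pluck = center + (h / 1000) * mainAxis`

  The prediction uses not the regression line *h = a d + b* but its
  **85% upper boundary**: the same line translated up by the one-sided
  85% quantile of the training residuals, so that for at least 85% of
  flowers the cut lands safely below the calyx rather than through it.
  Packaged per-species coefficients: pansy *h* = 0.36 *d* + 26.33
  (boundary + 43.20), snapdragon *h* = 0.38 *d* + 5.33 (+ 34.57),
  marigold *h* = 0.66 *d* + 7.10 (+ 37.91).

Deep detectors and segmenters are pluggable *inputs* (YOLO-format txt /
COCO JSON boxes, PNG masks); the package also ships a classical HSV
colour-blob fallback detector, a seeded synthetic RGB-D scene generator
with exact ground truth, mask cleaning (nearest-centroid component
selection), and a depth-ordered occlusion-skip rule so only flowers
with a complete point cloud are processed.

## Worked example

Simulate a bench scene (three flowers, 1 mm depth noise), run the full
cascade, and inspect the results:

```r
library(pluckvision)

flowers <- sampleFlowers(3, seed = 7)
scene   <- renderScene(flowers, noiseSdMm = 1, seed = 8, frameId = "bench01")
results <- processFrame(scene$frame, scene$detections, scene$masks)

results[[1]]
#> FlowerResult [marigold] status=ok: d=39.9 mm, h=64.2 mm, pluck=(0.179, -0.002, 0.557) m

resultsToDataFrame(results)[, c("label", "status", "diameter_mm", "h_mm",
                                "pluck_x", "pluck_y", "pluck_z")]
#>        label status diameter_mm  h_mm  pluck_x   pluck_y pluck_z
#> 1   marigold     ok       39.85 64.21  0.17888 -0.002198  0.5569
#> 2   marigold     ok       39.12 63.73 -0.01084 -0.087152  0.5533
#> 3 snapdragon     ok       26.60 44.68 -0.08295  0.107356  0.5526
```

Each row is one detection: the measured corolla diameter (the first
marigold is a 39.9 mm flower), the cut depth predicted from the
species' upper-boundary line (0.66 x 39.85 + 37.91 = 64.2 mm), and the
3D plucking point in metres, camera frame — the flower centre pushed
64.2 mm stem-ward along the estimated pose axis. Occluded or
depth-deficient flowers come back with status `occluded_skipped` /
`no_depth` instead of numbers, never as errors.

The calibration surface is available directly:

```r
cal <- loadPackagedCoefficients("marigold")
cal$boundary
#> BoundaryLine [marigold, packaged]: h = 0.6600 d +37.9100 (mm), coverage 0.85
predictH(cal$boundary, 36)
#> [1] 61.67
```

To refit on your own caliper measurements (CSV with
`species,d_mm,h_mm`), use `fitSpeciesModel()` + `upperBoundary()`, or
the command line: `inst/scripts/pluckvision calibrate --measurements
m.csv --coverage 0.85 --seed 1 --out calib.csv`. The same launcher has
`run` (process a frame from files) and `simulate` (write a synthetic
fixture directory) subcommands.

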