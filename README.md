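# orthocal

Colour calibration and colour-homogeneity assessment for UAV orthophoto
stacks.

Aerial surveys flown over several hours or days see changing weather, sun
position and colour temperature, so the frames that feed an orthophoto
mosaic disagree about the colour of the same ground. `orthocal` implements
a radiometric calibration and evaluation workflow for this problem:

- **3D thin-plate-spline (TPS) colour calibration.** A 24-patch
  ColorChecker chart imaged at the start of each flight provides 24
  correspondences between measured and reference RGB coordinates. A
  thin-plate spline in RGB space,
  `f(x) = c + A x + Σᵢ wᵢ U(‖x − sᵢ‖)` with `U(r) = −r`, maps every pixel
  of the flight's frames so the chart lands exactly on its reference
  values. The same estimator with the 2D kernel `U(r) = r² log r` drives
  the geometric superimposition. A 2D spline on K correspondences carries
  the classic `2(K + 3)` parameters: six global affine terms plus 2K
  radial coefficients.
- **Landmark superimposition.** Nine ground-control landmarks per image
  are averaged into a consensus configuration by generalized Procrustes
  analysis, and every image is unwarped to the consensus with a 2D TPS
  (backward mapping, bilinear resampling).
- **Colour-homogeneity statistic.** On the superimposed stack, n random
  points (default 300) are sampled in a central region of interest; at
  each point the mean of the 8 × 8 surrounding pixels is taken per image
  and channel, the across-image standard deviation is computed per
  channel, and the three channel SDs are reduced to one value per point:
  the RMS SD-RGB, in grey levels. The paired per-point values of the
  calibrated and uncalibrated conditions are compared with a two-sided
  Wilcoxon signed-rank test (exact null distribution for small n,
  Edgeworth-refined normal approximation otherwise).
- **Synthetic survey generator.** A seeded generator renders
  orthophoto-like stacks of one scene with known ground truth: smooth
  per-frame illuminant distortions (colour cast, per-channel gamma,
  gain/offset, vignette, sensor noise), an embedded chart that follows
  each frame's distortion, and landmark perturbations. It makes every
  stage testable end to end without real flights.
- **Flight-geometry calculators.** Closed forms for forward overlap,
  sidelap and ground sample distance from altitude, optics, sensor
  geometry and shot timing.

## Worked example

```r
library(orthocal)

# Flight geometry of a small-quadcopter survey
p <- flight_params(altitude_m = 22, focal_mm = 4.5, sensor_w_mm = 6.17,
                   sensor_h_mm = 4.56, image_w_px = 3968, image_h_px = 2976,
                   speed_m_s = 2, shot_interval_s = 3.34)
print(p)
#> Flight: 22.0 m AGL, 4.50 mm focal, sensor 6.17 x 4.56 mm, 3968 x 2976 px
#> Speed 2.00 m/s, shot interval 3.34 s
#> Forward overlap: 70.0%   GSD: 0.760 cm/px

# End-to-end synthetic run: simulate 15 frames, calibrate each against its
# chart, superimpose both conditions, compare homogeneity
cfg <- pipeline_config(file.path(tempdir(), "demo"), seed = 1)
run <- run_pipeline(cfg)
print(run$result)
#> Colour-homogeneity comparison: 300 points, 8 x 8 windows (seed 512007)
#>   calibrated       RMS-SD mean 1.57  sd 0.68  median 1.43
#>   non-calibrated   RMS-SD mean 8.62  sd 0.32  median 8.62
#> Paired Wilcoxon signed-rank test (two-sided)
#> W = 2 (smaller rank sum), n effective = 300, method = normal_approximation
#> p = 6.238e-51
```

The two summary lines are the homogeneity statistic per condition: after
calibration the typical across-image colour spread at a ground point drops
from ≈8.6 to ≈1.6 grey levels, and the paired test confirms the
improvement is systematic across the 300 sampled points. The run
directory holds every intermediate product: raw/calibrated/superimposed
frames as 8-bit LZW TIFF, the landmark file, chart annotation, per-point
CSV, JSON summary, report and log.

Individual stages are plain functions — `tps()` / `predict()`,
`measure_patches()`, `fit_color_calibration()`,
`apply_color_calibration()`, `procrustes_consensus()`,
`unwarp_to_consensus()`, `sample_points()` / `window_means()` /
`rms_sd()` / `wilcoxon_signed_rank()` — so any part of the workflow can
be used on its own (e.g. on real frames with a hand-made chart
annotation and landmark file).

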