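---
title: "Colour calibration and homogeneity assessment for orthophoto stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colour calibration and homogeneity assessment for orthophoto stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthocal)
```

## The problem

Orthophoto mosaics of agricultural or natural terrain are assembled from
many aerial frames acquired minutes to days apart. Illumination changes —
cloud cover, sun elevation, colour temperature — leave each frame with its
own radiometric signature, so the mosaic disagrees with itself about the
colour of the same ground, and any quantitative use of colour (vigour
indices, phenotyping, change detection) inherits that noise. `orthocal`
implements a chart-based calibration that removes the per-frame signature,
a landmark superimposition that puts all frames into one geometric frame of
reference, and a statistic that quantifies how colour-homogeneous the
resulting stack is.

## Thin-plate-spline colour calibration

The core estimator is the thin-plate spline fitted by `tps(source, target,
lambda)`. For K correspondences $s_i \mapsto t_i$ it returns the map

$$f(x) = c + A x + \sum_{i=1}^{K} w_i \, U(\lVert x - s_i \rVert),$$

with the biharmonic kernel $U(r) = r^2 \log r$ in two dimensions and
$U(r) = -r$ in three, subject to the side conditions $\sum_i w_i = 0$ and
$\sum_i w_i s_i = 0$ that strip any affine component from the radial part.
Coefficients come from the standard bordered system
$[[K + \lambda I, P], [P^\top, 0]]$, solved densely with one step of
iterative refinement; at the K ≤ 24 sizes used here this is exact to
machine precision and simpler to audit than a null-space decomposition.
Degenerate configurations (collinear in 2D, coplanar in 3D) are detected
by a singular-value test on the centred source points and rejected with an
explicit error, because the affine block of the system loses rank there.

Colour calibration is this estimator in RGB space: the 24 patches of a
ColorChecker chart measured in an acquired frame are the source, the
chart's published sRGB reference coordinates (bundled as
`reference_chart()`) are the target. With the default `lambda = 0` the
fitted map reproduces every patch exactly; `lambda > 0` (added to the
kernel diagonal, in squared 0–255 colour units) trades interpolation for
smoothness and is exposed for noisy chart captures. The smoothness of the
spline between control points is what lets 24 correspondences correct a
whole image: the model assumes the frame's distortion is a *smooth*,
global function of colour — true for white-balance casts, channel gammas
and exposure differences, not for local, spatially varying effects.

Patch measurement (`measure_patches()`) uses the central 80% trimmed mean
per channel of each annotated patch rectangle after shrinking the
rectangle by 20% per side. The trimmed mean is exact on flat patches and
robust to edge bleed and specular outliers; both fractions are fixed so
results are reproducible. Patch localisation is deliberately by
annotation file rather than automatic chart detection, which keeps the
calibration core small and testable.

Two conveniences sit on top: `apply_color_calibration()` maps a whole
image (optionally through a `lut_resolution`³ lattice with trilinear
interpolation — at resolution 33 the LUT path stays within one grey level
of direct evaluation for the smooth casts calibration produces), and
`calibration_error_percent()` scores held-out colours as the mean
Euclidean RGB error normalised by the cube diagonal $255\sqrt{3}$, in
percent. That normalisation is a package definition, made explicit here
because "percent error" is otherwise ambiguous: it is bounded in
[0, 100], symmetric in the channels, and zero exactly at perfect
reconstruction.

## Superimposition

`procrustes_consensus()` computes the average landmark configuration by
iterative generalized Procrustes analysis: translate to a common
centroid, scale to unit centroid size, rotate each configuration onto the
running mean (proper rotations only), re-average, repeat until the mean
moves by less than 1e-8 (at most 100 iterations). The initial mean is the
plain average of the pre-scaled configurations, which makes the result
invariant to input order in raw coordinates; under a common rotation of
all inputs the consensus rotates along (equivariance), which is the
behaviour a pixel-space target needs. Scaling is included by default
(classical full Procrustes) and the consensus is then rescaled to the
mean input centroid size and anchored at the mean input centroid, because
the unwarp target must live in pixel units; `scaling = FALSE` gives
partial Procrustes for stacks where scale is meaningful. For nominally
north-aligned orthophotos the rotations are near-identity and harmless.

`unwarp_to_consensus()` warps an image so its landmarks land on the
consensus, by backward mapping: a 2D spline is fitted from consensus to
image landmarks, evaluated at every output pixel centre, and the source
is sampled bilinearly. Out-of-source pixels receive a fill colour
(default black) and are flagged in a validity mask carried as an
attribute; the output canvas keeps the input size, and the homogeneity
sampler is responsible for staying inside valid pixels (windows touching
invalid pixels are rejected and redrawn, with the rejection count
recorded). Coordinates throughout the package are (row, col), 1-based,
with pixel centres at integer positions — the native R array convention.

## The homogeneity statistic and test

On a superimposed stack, `compare_conditions()` samples n (default 300)
distinct points uniformly from a region of interest shrunk by a margin of
half the window size, using a mandatory seed that is recorded in the
output. At each point and in each image the 8 × 8 window mean is taken
per channel (a point $(r, c)$ anchors rows $r-4\ldots r+3$ and columns
$c-4\ldots c+3$; the anchor is fixed so results are bit-reproducible).
Within each condition the sample standard deviation (n−1 denominator,
chosen for unbiasedness) across images is computed per channel, and the
root mean square of the three channel SDs gives one value per point — the
RMS SD-RGB, in grey levels. The same points are used for both conditions,
making the comparison paired; each condition's SD is computed within its
own images, which is the only reading that yields a paired per-point
test.

The paired values feed `wilcoxon_signed_rank()`: zero differences are
dropped, tied absolute differences get midranks, the statistic is the
smaller signed-rank sum, and the two-sided p is
$P(\min(W^+, W^-) \le w_{obs})$ under random signs. The null distribution
is computed exactly by convolution over the doubled ranks (equivalent to
enumerating all $2^n$ sign vectors) for $n \le 12$ or on request; larger
n use a normal approximation with tie correction, continuity correction,
and an Edgeworth fourth-cumulant term
($\kappa_4 = -\sum_i r_i^4 / 8$). The Edgeworth term is what keeps the
approximate p within 0.005 of the exact one already at n around 20–30;
it is an asymptotic correction for the body of the distribution and is
switched off deep in the tail, where it would exceed the leading Gaussian
term. If all paired differences are zero the test is degenerate by
construction and reports p = 1 with a flag rather than an error, since a
pipeline run at zero distortion severity legitimately produces exactly
identical conditions.

## The synthetic survey generator

No real flights ship with the package, so every stage is exercised on a
seeded generator with known ground truth. `make_base_scene()` builds an
orthophoto-like scene: a band-limited random texture in a green-dominated
palette (mimicking a set-aside grass field), nine high-contrast circular
landmark targets on a 3 × 3 grid, and a flat-patch reference chart in the
top-left corner whose measured values equal the reference table exactly.
`render_survey()` derives, per frame and via named substreams of the
master seed: an illuminant distortion, a small similarity transform of
the scene, and landmark measurement noise. The chart is re-stamped at its
fixed annotation after the geometric warp and before the illuminant, so
each frame carries an in-frame chart whose measured colours follow that
frame's distortion — the situation chart-based calibration assumes.

The illuminant model (`draw_illuminant_params()`) composes, in order: a
diagonally dominant 3 × 3 cast matrix (off-diagonals up to 0.08, diagonal
within ±0.05 at full severity), per-channel gamma in 1 ± 0.2, global gain
in 1 ± 0.15, offset in ±12 grey levels, a radial vignette
$1 - v\rho^2$ with $v$ up to 0.15, and Gaussian sensor noise with SD 2
grey levels — all magnitudes scaled linearly by a severity parameter in
[0, 1], with severity 0 the exact identity. Two of these choices deserve
justification. The overall magnitudes were fixed once so that the
uncalibrated RMS SD-RGB of a 15-frame stack at the default severity 0.5
falls in the mid-single-digit grey levels typical of real multi-day
surveys; this anchors the simulation's scale, and is a design choice of
the generator, not a claim of reproducing any particular field campaign.
The vignette ceiling is deliberately modest because consumer drone
cameras apply in-camera lens corrections, leaving only residual falloff —
and because a colour-space map cannot correct a spatially varying effect
at all, so the vignette's role is to inject a bounded amount of
structurally uncorrectable error rather than to dominate the budget.

What the generator does *not* emulate: perspective and structure-from-
motion artefacts (the geometric perturbation is similarity + jitter
only, enough to exercise superimposition without confounding the colour
comparison), BRDF and atmospheric effects, shadows that move between
frames, and the reconstruction stage of a photogrammetry engine.
Passing tests on this generator therefore demonstrate that the
calibration recovers smooth global colour distortions and that the
statistic detects the improvement — not that any specific real-world
error level will be achieved.

## Flight geometry

`forward_overlap()`, `side_overlap()` and `ground_sample_distance()` are
pinhole-camera closed forms. The along-track footprint uses the sensor
*height* (the 4.56 mm dimension of the default 6.17 × 4.56 mm sensor):
with the default 22 m altitude, 4.5 mm focal length, 2 m/s and a shot
every 3.34 s this yields the canonical 70% forward overlap configuration,
which is what identifies the height as the along-track dimension. GSD
uses the sensor width across the image width, in cm/pixel. Published GSD
figures for such surveys sometimes assume slightly different altitude or
rounding conventions, so small discrepancies against vendor flight-planner
outputs are expected.

## Problem sizes and reproducibility

The shipped tests and the acceptance script run entirely on synthetic
data at scene size 256 × 320 with 15-frame conditions, 300 sampled
points, 20-seed Monte-Carlo loops for distributional properties, and a
severity grid {0.25, 0.5, 1.0} for the calibration-accuracy study —
sizes chosen so the whole suite exercises every contract at full
statistical strength while remaining quick on a laptop. Every random
draw flows from explicit seeds through named substreams; the pipeline
(`run_pipeline()`) passes stage boundaries through written 8-bit files,
so a rerun with the same configuration reproduces every CSV/JSON output
byte for byte.

## Known limitations

- Calibration corrects smooth global colour maps only; spatially varying
  effects (vignette, shadows) and out-of-gamut clipping are not modelled,
  and gamut clipping is handled by plain truncation to [0, 255].
- The chart must be measurable in (or alongside) every frame; automatic
  chart detection is out of scope.
- The consensus target assumes landmark sets are complete and ordered
  identically across the stack; there is no support for missing or
  sliding landmarks.
- The homogeneity test treats sampled points as independent; spatial
  autocorrelation between nearby windows is not corrected for, which is
  one reason the sampler enforces distinct points and a margin but makes
  no further adjustment.
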