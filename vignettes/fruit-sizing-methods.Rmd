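---
title: "Measuring on-tree mango fruit from night RGB-D imagery: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring on-tree mango fruit from night RGB-D imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MangoSizer)
```

## The measurement problem

Orchard management wants fruit size distributions without hand calipers:
tray-insert ordering, maturity monitoring and harvest planning all key on
lineal fruit dimensions, and mango mass itself is well predicted by
allometry on those dimensions. A vehicle-mounted RGB-D camera imaging the
canopy at night (LED illumination, one frame per tree at roughly 2 m)
can deliver this *if* three things are solved: finding fruit whose full
contour is visible, segmenting that contour to the pixel, and converting
pixel extents to millimetres — which requires the camera-to-fruit
distance that the depth channel provides.

The estimator is deliberately biased toward precision over recall: a
fruit sizing survey needs a *sample* of cleanly measured fruit, so false
positives (clutter or partially occluded fruit measured as whole fruit)
are far more damaging than missed detections.

## Pipeline

`sizeFrame()` wires the stages in order; each is exported and testable
on its own.

1. **Registration and cropping** (`registerDepthToRGB()`,
   `cropRGBToDepthFOV()`). Depth pixels are back-projected with the
   depth camera's pinhole model (depth read as plane-to-plane distance),
   rigidly transformed, and re-projected onto the RGB grid; where two
   depth samples land on one RGB pixel the nearer surface wins, which is
   the occlusion-correct choice. The RGB raster is cropped to the depth
   camera's angular field first, since the colour camera sees a wider
   horizontal field than the time-of-flight sensor.
2. **Un-mirroring** (`mirrorHorizontal()`): the sensor presents imagery
   mirrored for its original gaming use.
3. **Detection** (`detectFruit()`): a sliding-window cascade of boosted
   decision stumps over HOG features (6 px cells, 9 unsigned orientation
   bins, 2×2-cell blocks, L2-normalized), run over a factor-1.2 scale
   pyramid covering objects of 40–160 px. A detection is reported only
   where at least `mergeThreshold = 8` raw windows agree — the
   neighbor-count rule that suppresses isolated false alarms.
4. **Segmentation** (`segmentCandidate()`): each detection box is
   doubled about its centre; within the snip, Otsu's threshold on the
   CIELAB L\* plane separates the brightly lit convex fruit from darker
   foliage, a fixed chroma gate (−25 ≤ a\* ≤ 25, −20 ≤ b\* ≤ 35,
   inclusive) removes bright but green/yellow foliage, connected
   components under 300 px are dropped and enclosed holes under 300 px
   filled.
5. **Stalk removal** (`removeStalks()`): a 1D run-length filter zeroes
   non-zero runs shorter than w = 8 px (≈ 14 mm at 2 m), row-wise then
   column-wise — pendulous stalks are thin and vertical, so the row pass
   removes them while line-wise operation preserves the fruit outline —
   followed by a radius-1 disk dilation that restores the fruit tip the
   filter truncates.
6. **Completeness gate** (`fitMomentEllipse()`, `gateComponent()`): the
   component's moment ellipse (same first and second moments as the
   pixel set) must satisfy all four criteria — area within
   [1000, 8000] px, area ratio r = 4A/(πab) > 0.97, eccentricity
   ε ≤ 0.75, and bounding-box long side less than 4 px over the fitted
   major axis. Occlusion leaves a concave contour whose pixel set
   underfills its own fitted ellipse, so r is the workhorse criterion.
7. **Sizing** (`centerDepth()`, `measureComponent()`, `pixelsToMm()`):
   distance is the mean of the valid entries of the 2×2 depth block at
   the bounding-box centre (readings under 0.8 m are excluded as outside
   the sensor's working range), and the thin-lens relation
   f / D = image size / real size converts the box's vertical extent to
   length through the y-axis focal length and its horizontal extent to
   width through the x-axis focal length.

Mass then follows from allometry (`massLW2()`, `massLWT()`,
`massLWAvg()`; dimensions in cm, grams out), and `sampleSize()` gives
the survey size n = (1.96·SD/e)² needed to pin the population mean.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| cell size (HOG) | 6 | px | the load-bearing descriptor resolution for ~50–120 px fruit |
| merge threshold | 8 | windows | precision-first detection regime |
| box expansion | 2 | — | guarantees the snip covers the whole fruit |
| a\*, b\* gates | [−25, 25], [−20, 35] | CIELAB | separates lit fruit from foliage chroma |
| min area (morphology) | 300 | px | speckle and hole scale at 2 m |
| stalk width w | 8 | px | ≈ 14 mm at 2 m: thicker than any stalk, thinner than any fruit |
| gate area | [1000, 8000] | px | whole-fruit sizes at ≈ 2 m |
| gate r | > 0.97 | — | whole convex fruit fill their moment ellipse |
| gate ε | ≤ 0.75 | — | mango outlines are near-circular; clusters and leaves are not |
| bbox − major axis | < 4 | px | residual thick stalk ends inflate the box, not the ellipse |
| min depth | 800 | mm | sensor working-range floor |
| depth bias | 0 (19.1 for the characterized unit) | mm | device-face-to-sensor offset, removable once measured |

The CIELAB thresholds only make sense on the signed L\* ∈ [0,100] scale
under D65 — `toCielab()` uses exactly that convention, and all bounds
are inclusive.

## The synthetic scene generator

`sampleScene()`/`renderScene()` emulate the night-imaging conditions the
pipeline was designed for: bright convex elliptical fruit (CIELAB chroma
sampled inside the segmentation gate with margin, |a\*| ≤ 15,
0 ≤ b\* ≤ 25; L\* ≈ 72–84 with convex shading) over darker foliage whose
chroma lies outside the gate (a\* ≤ −30 or b\* ≥ 45), thin pendulous
stalks (3 px, within-gate chroma, removable only by the run filter),
leaf-shaped partial occluders, camera-to-fruit distances of 1–3 m, and
integer-millimetre depth with truncated Gaussian noise (σ = 11 mm
reproduces the bias-corrected depth RMSE measured on fruit for this
sensor class) plus optional dropout. Fruit dimensions default to the
field ranges (length 60–160 mm; width 0.75–0.85 of length, clipped to
50–130 mm — the aspect keeps true eccentricity below the 0.75 gate, as
the gate's design presumes for mango).

Two generator choices deserve emphasis:

* **Occlusion is a leaf-shaped bite, not a straight cut.** A straight
  band truncation leaves the area ratio above 0.97 until ~25% of the
  fruit is covered (measured on rendered ellipses: r = 0.982 at 15%,
  0.975 at 20%), whereas an elliptical occluder entering from a side —
  how foliage actually occludes — leaves a concave notch and gives
  r = 0.958 at 15% and 0.935 at 20%. The gate's published constants were
  tuned on real foliage occlusion, so the bite geometry is the faithful
  emulation.
* **Training snips come from the same renderer.** Detector positives are
  windows centred on rendered fruit at 0.7–0.9 of the window; negatives
  are fruit-free canopy crops plus hard negatives (off-centre or
  off-scale fruit) that teach the cascade to fire only on centred whole
  fruit. Every snip also contributes its horizontal mirror, keeping the
  learned cascade approximately mirror-equivariant.

What the generator does **not** emulate: specular highlights, real leaf
texture and venation, wind blur, sunlight interference with the
time-of-flight return, cultivar-specific (non-ellipsoidal) fruit shapes,
and the true chroma statistics of night foliage, which the source
imagery never quantified. Green tests therefore certify the algorithmic
contracts and the geometry/optics chain, not field performance: the
published field accuracies (length RMSE 4.9 mm, width 4.3 mm against
calipers) required the orchard image set and are not reproducible at
desk scale.

## Numerical choices

* **Otsu** runs on a 256-bin histogram of L\* over [0, 100]; ties break
  toward the lower threshold; the brighter class is foreground. A
  constant channel is flagged degenerate rather than thresholded.
* **Connectivity** is 8 for foreground components and 4 for background
  holes (the standard duality). Hole "closing" is area-based filling of
  enclosed background components under 300 px, matching the stated
  pixel-count criterion rather than a structuring element.
* **Moment ellipse**: axes come from the eigenvalues of the second
  central moment matrix with a +1/12 per-axis pixel-extent correction,
  so rasterized shapes are recovered without size bias; collinearity is
  judged on the raw moments *before* that correction. Axes are full
  lengths (a = 4√λ₁).
* **Line-filter borders** count as zero delimiters — otherwise a stalk
  leaving the snip would survive.
* **Depth lookup** floors the box centre and averages the centre pixel
  plus its right/down neighbours (the 2×2 block anchored at the centre),
  ignoring invalid zeros; all-invalid blocks reject the candidate.
* **Registration collisions** keep the smaller depth (nearer surface).
* **sample size** rounds to the nearest fruit (a ceiling mode exists for
  conservative planning); the width evaluation rule resolves ties to W.

## Design decisions on genuinely open points

* **Focal-axis orientation.** The y-axis focal length (3.5157 mm) maps
  the vertical pixel extent to fruit *length* and the x-axis focal
  length to *width*: fruit hang vertically by the weight of the stalk,
  and the published one-pixel worked example for length uses the y-axis
  value. The alternative reading of the calibration prose (fx → length)
  is rejected on that arithmetic.
* **HOG "box size".** The source phrase "box size of 6 × 6" is read as
  2×2-cell block normalization with 6×6 px cells — the standard layout
  in which cell size is the load-bearing number.
* **Detection-box reporting.** Raw hits are merged with stride-density
  weights (a pyramid level at scale r contributes hits every cell/r
  pixels, so hits are weighted by 1/r²) and the merged window is shrunk
  to 0.7 of its side — the geometric mean of the trained fruit's window
  fill (0.78 of height, 0.61 of width) — since the cascade window
  deliberately includes context around the fruit.
* **Boundary rejection.** A component touching the expanded-snip edge is
  rejected ("boundary"): its contour may be clipped by the crop, and a
  clipped fruit can pass the four published criteria while measuring
  short. This is an added guard, not a change to the published gate.
* **Duplicate capture.** Doubled boxes from adjacent detections can
  segment the same fruit twice; accepted components overlapping by more
  than half the smaller's area are deduplicated keeping the larger.
* **Mirroring default.** Real frames default to `mirror = TRUE`
  (sensor convention); the renderer already produces presentation-
  oriented frames, so `syntheticPipelineConfig()` sets it off.

## Problem sizes in the shipped tests

The test suite renders 400×320 px scenes (the published optics behind a
smaller sensor, principal point centred) — large enough for three to
eight well-separated fruit at 1.5–2.5 m. End-to-end properties use 100
single-fruit noiseless scenes (length RMSE must stay within the 2-pixel
equivalent, ≈ 3.5 mm at 2 m, with zero acceptances of fruit occluded by
≥ 20%), and the depth-noise study uses 600 Monte-Carlo draws at σ =
11 mm, which must agree with the first-order sensitivity ΔL = L·ΔD/D
(± 0.55 mm per 100 mm at 2 m). The reference detector trains on 80
positive and 400 negative renderer snips in a few seconds.

## Known limitations

* Cascade-with-stumps detection saturates near 97% precision at the
  single-window level on this synthetic task; the zero-false-positive
  regime is a property of the full chain (neighbor-count merging plus
  the ellipse gate), as it was in the field system.
* Sizing reports the *imaged* width, which for an unconstrained hanging
  fruit lies anywhere between true width and thickness; evaluation
  against calipers must use the closer of the two
  (`widthReference()`), and single-view thickness is out of reach.
* The thin-lens conversion uses the plane distance the sensor reports,
  uncorrected for ray obliquity, and a first-order radial distortion
  model (K1, K2) — both adequate at the 1–3 m working range, neither
  beyond it.
* Fruit smaller than ~45 px (far or small fruit) fall below the
  detector's pyramid floor and the gate's area floor; they are missed,
  not mismeasured — consistent with the sampling-survey intent.
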