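---
title: "Measuring microvascular blood flow in unstable vessel video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring microvascular blood flow in unstable vessel video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scleraflow)
```

## The measurement problem

Video of the bulbar conjunctiva and sclera shows surface microvessels whose
blood flow reflects systemic microcirculation. The video is hard to use
directly: the eye cannot be fixed, so the field of view translates from
frame to frame (occasionally jumping far away), sharpness and illumination
drift, and only part of each frame holds enough contrast to support
analysis. `scleraflow` implements a descriptive cascade that turns such a
sequence into quantitative flow and topology measurements:

1. **Informative-region detection.** Per frame, the gradient magnitude is
   the per-pixel maximum of the two 3×3 Sobel responses. The Michelson-type
   contrast of the gradient image, $C = (I_{max} - I_{min}) / (I_{max} +
   I_{min})$, flags frames with $C < 0.3$ as uninformative. The gradient
   image is binarized at the knee of its cumulative histogram — the bin at
   maximum perpendicular distance from the chord joining the first and last
   occupied bins — debris below `min_object_px` (default 20 px) is removed,
   objects are linked by a 2 px dilation, and the bounding box of what
   remains is the region of interest (ROI).
2. **Fragmentation.** The intensity-weighted centroid of the informative
   pixels is tracked across frames; a fragment ends when the centroid drifts
   more than 100 px (Euclidean, measured against the fragment's first
   frame) or the ROI disappears. Each fragment is cropped to a common box:
   corner extremes over all per-frame ROIs, with the minimum per-frame
   width/height as the common size, centered on each frame's centroid.
3. **Stabilization.** Either zero-normalized cross-correlation of a
   reference patch (the centered 50% of the first frame's ROI) against each
   frame, or Shi–Tomasi corners tracked with pyramidal Lucas–Kanade flow,
   with the per-frame offset taken as the component-wise median of tracked
   displacements. The keypoint method falls back to correlation when fewer
   than 4 points survive. Frames are shifted back by the rounded offsets
   and cropped to the common valid region.
4. **Vessel masking.** The default segmenter is a deterministic multi-scale
   Hessian (Frangi-type) tubularness enhancement over widths ≈ 2–12 px,
   calibrated so that an automatic operating point (Otsu on the response
   histogram) maps to probability 0.5, with the polarity 0 = vessel. An
   optional sliding-window patch classifier (single-hidden-layer network on
   raw patches, trained exclusively on phantom scenes with flip/turn
   augmentation) mirrors the two-class window framing used with
   convolutional segmenters; it exists to exercise that interface at desk
   scale, not to compete with a trained network.
5. **Flow measurement.** Outside a slightly dilated mask the background is
   replaced by the mean of a 5 px halo ring; brightness is then equalized
   by iterating $I \leftarrow I^{\ln\gamma / \ln \bar I}$ until the mean is
   within $10^{-3}$ of $\gamma = 0.5$. Dense optical flow between
   consecutive frames uses Farnebäck polynomial expansion (pyramid scale
   0.5, 3 levels, window 15, 3 iterations, poly neighborhood 5, σ = 1.1).
   The flow magnitude along the 1-px skeleton midline is the relative
   linear speed; volumetric speed is $Q = v \cdot S$ with the circular
   cross-section $S = \pi (w/2)^2$ and the width $w$ from the Euclidean
   distance transform ($w = 2d - 1$). Topology metrics — total and
   per-segment length, branchiness (branch nodes per unit length),
   compactness ($4\pi \cdot \text{area} / \text{perimeter}^2$) and
   tortuosity (arc / chord) — come from the skeleton graph.

## The phantom generator

Because no clinical recordings ship with the package, every stage is
validated against a synthetic phantom with complete ground truth: the tube
tree and widths, the binary mask and subpixel centerline, per-frame camera
offsets, and per-segment advection speeds.

The scene is a connected tree of tube segments (smooth polylines, widths
2–12 px) on a canvas of at least 64×64. Layouts: `"random"` (a root tube
with children attached at interior points), `"straight"` (a horizontal tube,
optionally with two short side branches near its ends whose junctions give
registration the static anchor points that vessel branch nodes provide in
real scenes), and `"y"` (a parent that bifurcates into two children, used
for flow-conservation checks). With `conserve_flow = TRUE`, children of a
parent share the velocity $v_c = v_p S_p / \sum S_c$, so $Q$ balances at
the bifurcation by construction.

Rendering choices worth knowing about:

* **Texture.** The tube interior carries band-limited speckle advected
  along the centerline by linear interpolation in arc length. The speckle
  modulates a static cylindrical absorption profile by a modest fraction,
  the way red-cell flux modulates capillary darkness — deliberately *not*
  the dominant structure in the scene, so that registration locks onto
  static anatomy rather than onto the moving blood column. Nearest-neighbor
  resampling was rejected: on oblique tubes the rounding of the arc-length
  coordinate leaves a static 1-px staircase carrier that any optical-flow
  method locks onto.
* **Walls.** Tube boundaries get a ~1 px anti-aliasing coverage ramp. A
  hard pixel staircase on oblique walls is static high-frequency structure
  no real camera produces, and it pins the flow estimate to zero along the
  whole vessel.
* **Background.** The background level is 0.6 — near the equalization
  fixed point $\gamma = 0.5$, which is the operating regime the brightness
  alignment presumes — with static band-limited texture of amplitude 0.12
  (scleral tissue is not optically flat). A perfectly flat background makes
  camera translation and intra-vessel advection mathematically inseparable
  on single-tube scenes; real scenes do not have that degeneracy.
* **Defects.** Per-frame integer translation jitter (SD 3 px by default),
  optional persistent jumps > 100 px at chosen frames, sinusoidal
  illumination drift with a mild lateral ramp (amplitude 0.05), and
  per-frame Gaussian defocus drawn from a range. A single integer seed
  fixes the entire realization bitwise.

What the phantom does **not** emulate: sensor noise, pulsatile speed
variation, vessel diameter change over time, specular reflections, and
out-of-plane motion. Passing the phantom suite therefore demonstrates that
the cascade is internally correct and recovers known kinematics under the
modeled defects — not that it is robust to every clinical artifact.

## Numerical choices and degenerate inputs

* Histogram knee: 256 bins on $[0, \max g]$, chord between first and last
  nonempty bins, ties toward the lowest bin; a single occupied bin returns
  its own value.
* The centroid uses the standard weighted mean (weights scaled so the
  maximum in-ROI intensity has unit weight). A literal variant that divides
  by the pixel count is available behind `literal_n = TRUE`.
* Correlation: the fast path (FFT numerator, integral-image denominators)
  agrees with the direct double sum to ~1e−12; ties at the peak break
  toward the smallest offset; zero-variance patches are an error, blank
  windows correlate as 0.
* Farnebäck warps the expansion coefficients with bilinear interpolation —
  rounding to the nearest pixel biases small displacements by ~20% — and
  weights the solve window with a Gaussian (σ = winsize/5), which keeps
  nearby static structure from bleeding into the estimate. Degenerate 2×2
  systems (determinant ≤ 1e−12) leave the prior displacement unchanged.
* Skeletons: Zhang–Suen thinning; branch/end classification by the
  Rutovitz crossing number (raw 8-neighbor degree misfires on diagonal
  staircases); branch pixels within ~2 px merge into one junction node;
  terminal spurs shorter than 8 px (thinning artifacts of wide tubes) are
  pruned; arc length uses stride-3 chord subsampling because raw
  8-connected stepping overestimates digitized curve length by ~5–8%.
* Flow summaries per segment trim 12 px of arc length at each end
  (`profile_summary()`): the displacement solve adjacent to branch nodes,
  vessel ends and mask boundaries mixes in static structure and reads low,
  and flow at branch nodes is genuinely discontinuous.
* The background fill uses the mask dilated by 2 px so the fill boundary
  clears the true wall even when the mask runs a pixel thin; a constant
  step cut into moving texture otherwise biases the flow toward zero.
* Brightness equalization is a no-op (with a warning) for all-zero or
  all-one frames; an empty mask fills the frame with its global mean.

## Problem sizes

The shipped tests and the acceptance script run entirely on phantoms:
canvases of 160–192 px, 2–60 frames, 1–3 vessel segments, ten seeded scenes
for segmentation quality. These sizes keep the full suite under a minute on
one core while leaving every measured quantity well away from its tolerance
(velocity within ~6–10% of truth against a 15% band, Dice ≈ 0.92 against a
0.8 bar, offset recovery at 100% against a 95% bar).

## Known limitations

* Translation-only registration: rotation and scale are out of scope.
* Speeds are relative (px/frame) unless `um_per_px` and `fps` are supplied
  to `calibrate()`; no attempt is made to infer absolute calibration from
  the imagery.
* Farnebäck underestimates flow in tubes much narrower than the solve
  window (measurably below ~6 px width at the default window 15), and
  within ~12 px of junctions; wider vessels and segment interiors are
  measured accurately.
* The vesselness segmenter assumes tubular, roughly uniform-polarity
  vessels; it is not a substitute for a trained segmentation network on
  clinical imagery, and no claim is made about clinical accuracy.
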