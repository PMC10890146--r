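---
title: "Methods: projector-camera calibration and histology label transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: projector-camera calibration and histology label transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Point-based optical tissue sensing (e.g. diffuse reflectance spectroscopy on
breast lumpectomy specimens) needs ground-truth pathology labels for each
measured location. A point-projection-mapping (PPM) system projects the
selected measurement locations as light dots onto the specimen so they can be
tracked without inking the tissue; the measured slice is then processed into
an H&E section that a pathologist annotates. Producing a label for each
measurement requires (i) a geometrically calibrated projector–camera pair and
(ii) a deformable registration from the specimen snapshot to the histology
image, because fixation and sectioning shrink, stretch and compress the
tissue. `ppmap` implements both halves plus the label-transfer step, and a
synthetic-phantom generator that stands in for hardware and patient data.

## Base-plane calibration

A downward-facing depth camera over a work surface should see a constant
depth map; in practice the surface is slightly inclined. We model it as
$a x + b y + z + c = 0$ and fit $(a, b, c)$ by minimising the mean squared
vertical residual $\frac1n \sum_i (a x_i + b y_i + z_i + c)^2$ over randomly
sampled valid pixels of a frame average. The objective is linear in the
parameters, so the normal-equations solution is exact and no iterative
solver is used. (The vertical residual differs from the true point-to-plane
distance by the factor $1/(a^2+b^2+1)$; for the near-horizontal surfaces
this system calibrates the two are numerically indistinguishable, and the
vertical form is the one the correction step inverts exactly.) Corrected
depth is $z^{new} = z + a x + b y + c$: zero on the surface, object height
above it elsewhere.

Pixel coordinates are 0-based column/row indices in pixel units; the plane
model is unit-agnostic in $(x, y)$, so slopes are per-pixel unless the
caller rescales. Sampling defaults to 10 000 points (seeded), or all valid
pixels if fewer; depth dropouts are excluded by a validity mask with an
optional $[z_{min}, z_{max}]$ gate.

## Projector calibration

Camera space and projector space are related by a rigid transform
$P_p = R P_c + T$. Point pairs come from a projected checkerboard observed
at several heights and orientations (12 inner corners per configuration;
corner detection is out of scope — the estimator consumes coordinate
tables). The least-squares rotation and translation are obtained in closed
form by orthogonal Procrustes (SVD of the centered cross-covariance); an
optional derivative-free Nelder–Mead polish over an axis-angle
parameterisation is available but cannot improve the closed form on this
objective — it exists because per-instance refinement is how such systems
are often tuned in the field. For planar (single-board) configurations the
third singular direction is indeterminate and the standard sign-flip yields
the proper rotation; a negative determinant on full-rank data indicates
genuinely mirrored correspondences and is an error. Accuracy is reported as
$\mathrm{RMSE} = \sqrt{\tfrac1n\sum \lVert R p_c + T - p_p\rVert^2}$ in mm.
The test suite checks this estimator against Horn's quaternion method, an
independent closed form.

## Preprocessing

The registration operates on single-channel images in $[0,1]$ at a fixed
256 × 192 grid. The specimen snapshot is converted to grayscale using the
HSV **saturation** channel $S = (\max - \min)/\max$ (0 where $\max = 0$):
on H&E-like material this produces intensity levels comparable to the
histology image, which keeps the mutual-information objective informative
across modalities. The histology image uses Rec. 709 luminance (the channel
mix is not prescribed anywhere; luminance is the documented default).
Downsampling is exact box-overlap area averaging (anti-aliased, mean
preserving — protecting the MI histograms), upsampling is bilinear; aspect
ratio is *not* preserved, matching a fixed network-style input grid.
Foreground masks for the Dice score are Otsu-thresholded, reduced to the
largest 4-connected component, holes filled.

## Deformable registration

The registration estimates a dense displacement field (DDF) $\varphi$ on
the moving image's grid under the backward convention:
$M(\varphi)(x,y) = M(x + u(x,y),\, y + v(x,y))$ with bilinear sampling and
boundary clamping. Backward warping is the convention that resamples
without holes; POI masks are warped by the same operator (nearest-neighbor
sampling so label codes are never interpolated). Histology is the fixed
image by default — it is far easier to push measurement-area disks through
the DDF than to warp microscopic structure the other way.

The reference approach in this application family is an amortised
convolutional estimator (VoxelMorph-style) trained with a mutual-information
loss; its weights are not available, and the contract is simply "produce a
DDF maximising MI". We therefore fit each image pair directly:

* objective: $\mathrm{MI}(F, M(\varphi)) - \lambda \cdot
  \overline{\lVert\nabla\varphi\rVert^2}$, with MI in bits from a
  hard-binned 32 × 32 joint histogram on $[0,1]$ and a diffusion
  (squared-gradient) penalty averaged over forward-difference edges;
* parameterisation: a control-point grid (spacing 16 px) bilinearly
  upsampled to dense form, in a 3-level coarse-to-fine pyramid
  (64 × 48 → 128 × 96 → 256 × 192), the coarser solution upsampled and
  doubled at each promotion;
* optimiser: greedy coordinate ascent over control points with step halving
  (4, 2, 1, 0.5 px at the coarsest level), accepting only strict
  improvements, so the regularised objective is monotonically nondecreasing
  by construction. The per-level loop runs in C++ with incremental joint
  histogram and penalty updates (a control-point move only touches its
  bilinear support), which is what makes per-pair optimisation affordable
  (~10 s per pair on one CPU).

The loss MI and the reported metric MI share one implementation. Defaults:
32 bins (unstated in the reference workflow; 32 balances histogram
occupancy at 49 152 pixels against discriminative power), $\lambda = 0.05$
(no smoothness term is stated anywhere; 0.05 suppresses histogram-gaming
deformations while letting 8 px warps through), sweep cap 10 per step size
(a cap hit while still improving returns the best-so-far field with a
warning). The optimiser is fully deterministic; the config seed exists for
interface stability and for stochastic extensions.

MI is a blunt instrument: it rewards any deformation that sharpens the
joint histogram, not only geometrically correct ones, so interior
displacements are only softly constrained on weakly textured images. The
acceptance suite therefore scores registration by foreground Dice and by
direction of MI change, not by pointwise field error.

## Label extraction

POI dots are detected from the difference of luminance between the
with-dots and without-dots snapshots, thresholded at mean + 3 SD (the dots
occupy a negligible fraction of the frame, so global statistics approximate
the background), 4-connected components below 5 px discarded, centroids
taken as centers. Components more than twice the median area trigger a
merged-dot warning. Measurement areas are disks of the probe radius
(configurable; no standard value exists — probes differ) rasterised by the
pixel-center-inside-circle rule; overlapping disks are an error because
measurement areas must be distinct. After warping into histology space the
per-POI percentage of each annotated class is
$100 \cdot |{\rm disk}_k \cap {\rm class}_c| / |{\rm disk}_k|$, computed
over the *histology-space* disk (that is where the overlay happens; the
warped disk may legitimately deform). Every legend class is reported,
including 0%; percentages sum to 100 exactly; disks landing entirely on
unannotated background are flagged, never dropped.

## The synthetic world

The generators state one fixed world; none of their defaults were tuned
against test outcomes.

* **Depth scenes** — plane $(a,b,c) = (0.05, -0.03, -500)$: a ~0.5 m
  working distance with a few-degree tilt, typical for a downward RGB-D
  rig; Gaussian sensor noise SD 0.5 mm (consumer depth-camera class);
  optional 10 mm box. The depth value is stored as the camera-space height
  coordinate (objects raise $z$), making "corrected box height = +10 mm"
  literal.
* **Calibration pairs** — 3 × 4 inner-corner board, 20 mm pitch, 12 pairs
  per configuration, random pose (full in-plane rotation, ±0.15 rad tilt,
  0–100 mm height), true transform 30° about $z$ plus $T = (10, 5, 2)$ mm.
* **Deformation** — seeded white noise smoothed with a Gaussian
  (SD = scale/2, scale 32 px), smoothstep-tapered to zero within one scale
  of the border (keeps the specimen in frame), rescaled so the maximum
  magnitude equals the amplitude exactly (default 8 px — the magnitude
  class of fixation/sectioning distortion at this working resolution).
* **Specimen quartet** — elliptical phantom with fat / connective / tumor
  analog regions whose colors give distinct saturation levels
  (0.60 / 0.42 / 0.17 vs 0 background) and distinct histology intensities
  (0.85 / 0.55 / 0.30 vs 0.05); 5 POIs anchored one-per-region with seeded
  ±2 px jitter; dots of radius 3 px; probe radius 5 px. The histology image
  and annotation raster are the class layout pushed through the true field,
  so the true DDF is exactly the field the registration should recover; the
  analytic center mapping inverts the backward field by fixed-point
  iteration.

What the phantoms do **not** emulate: H&E texture, stain variation, tears
and holes, megacassette slide splitting, specular highlights, perspective
parallax. A green registration criterion therefore establishes that the
optimiser recovers smooth in-plane deformations between modality-styled
renderings of the same anatomy — not clinical-grade performance on real
slides, whose before/after Dice and MI distributions cannot be reproduced
without the (undeposited) study data.

## Numerical choices and edge cases

* All coordinates are 0-based, $(x, y)$ = (column, row), pixel centers at
  integers — everywhere, including file formats.
* Warping clamps out-of-bounds samples to the boundary value; label masks
  use nearest-neighbor under the same convention.
* MI returns 0 for any constant image; Dice of two empty masks is defined
  as 1.
* The plane and Procrustes solvers reject < 3 points and collinear
  geometry (relative condition / singular-value thresholds 1e-12 / 1e-9).
* Equality acceptance in the optimiser requires improvement > 1e-12 to keep
  the trace strictly monotone under floating-point noise.
* Rasters travel as ASCII PNM (P2/P3), depth as 16-bit ASCII PGM in 0.1 mm
  steps, fields as a two-plane text format, models as JSON — this
  deployment targets environments without binary image libraries, and all
  fixtures must be generatable as plain text.

## Known limitations

Per-pair optimisation is slower than an amortised network at inference
(seconds, not milliseconds) and, like the MI objective itself, can drift
interior pixels on texture-poor regions. The rigid calibration model
carries no lens-distortion or projector-intrinsics terms. The label
pipeline assumes the with/without-dot snapshots are pixel-aligned, as they
are when captured back-to-back by a fixed rig.
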