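---
title: "Models, parameters and validation design in stereospine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and validation design in stereospine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`stereospine` localizes anatomical surface features of the exposed spine
in 3D from two calibrated gray-scale camera views. This vignette explains
the models behind each stage, the parameters that matter (with units and
defaults), the design choices made where the design was genuinely open,
what the synthetic validation scenes do and do not represent, and the
package's known limitations.

## Geometry

**Camera model.** Metric pinhole cameras: focal lengths `(fx, fy)` in
pixels, principal point `(cx, cy)` in 0-based pixel coordinates (origin
top-left, x rightward, y downward), an orthonormal world-to-camera
rotation and a camera centre in millimetres. Lens distortion is not
modelled; it is treated as one of the noise sources that the triangulation
error absorbs.

**Fundamental matrix.** For a calibrated rig,
`F = K2^-T [t]x R_rel K1^-1` (unit Frobenius norm, largest element
positive, so the matrix is a deterministic function of the rig). An
uncalibrated path, `estimate_fundamental()`, implements the normalized
8-point algorithm with rank-2 enforcement; metric (millimetre)
triangulation requires the calibrated path, which is why the pipeline
takes a `stereo_rig`.

**Rectification.** `compute_rectification()` follows the projective
(epipole-to-infinity) scheme: translate the second image's centre to the
origin, rotate the epipole onto the positive x-axis, and apply
`G = I; G[3,1] = -1/f` to send it to infinity. The matching homography for
the first view is `A %*% H' %*% M`, where `M` satisfies `F = [e']x M` and
the affine row `A` minimizes the sum of squared distances between the
transformed correspondences — the horizontal-disparity criterion. Inside
`process_frame_pair()` the correspondences for this least-squares step are
synthesized by projecting a 3D grid around the convergence point of the
two optical axes; with a calibrated rig these are exact, and the measured
residual row misalignment of ground-truth points is below 0.1 px
(typically ~1e-12 px). Epipoles inside an image make the warp unbounded
and are rejected.

**Midpoint triangulation.** Matched pixels back-project to rays `C1x1`
and `C2x2`. The closest points of the two rays are found in closed form;
the reconstructed point is their midpoint and the *triangulation error*
is the length of the connecting segment `Vp` in mm. Rays with
`|sin(angle)| < 1e-8` are rejected ("parallel rays") rather than
returning enormous coordinates. The closed-form skew-line distance
`|(C2-C1)·(d1×d2)|/|d1×d2|` serves as an independent oracle in the tests
(agreement to 1e-12 relative).

## Preprocessing

* **CLAHE** (`clahe()`): 256-bin tile histograms, clip limit expressed as
  a *fraction of tile pixels* (default 0.03), clipped excess redistributed
  uniformly (the "uniform histogram shape"), bilinear blending between the
  four surrounding tile mappings. The tile grid is not dictated by the
  method description, so the common 8×8 toolbox convention is the default,
  configurable. `return_tiles = TRUE` exposes the clipped
  (pre-redistribution) tile histograms so the clip bound is auditable.
* **Otsu threshold** (`otsu_threshold()`): the 8-bit level maximizing the
  between-class variance, with classes `value < L` and `value >= L` and
  ties broken toward the lowest level. With these semantics the selected
  level of a clean bimodal image lies strictly between the modes.
* **Segmentation** (`segment_spine()`): the thresholded foreground is
  region-grown by 8-connected flood fill from a seed (default: the pixel
  of the largest foreground component nearest its centroid); the image is
  multiplied by the binary mask and the mask's bounding box replaces the
  manual crop of an interactive workflow, so the pipeline runs unattended.
  Keypoints detected in the crop are projected back by the ROI offset.
  Detections within `mask_margin` (default 8 px) of the mask boundary are
  discarded: the mask edge itself generates spurious image structure.

## The four detectors

All detectors operate on the CLAHE-enhanced, masked, rectified image and
share one matching path.

* **Hessian blob detector (SURF-style).** Box-filter approximations of
  the second Gaussian derivatives on an integral image, combined as
  `det = Lxx·Lyy − (0.9·Lxy)²`, with responses normalized by filter area
  and computed on the 0–255 intensity scale. The filter ladder uses side
  lengths `6·2^(o−1)·k + 3` for octave `o = 1..4` and scale `k = 1..6`
  (9, 15, …, 39; 15, 27, …, 75; …), 3×3×3 non-maximum suppression inside
  each octave, and the feature threshold 600. The nominal equivalent
  Gaussian scale is `1.2·L/9`; empirically the dense response argmax for a
  Gaussian blob of scale *s* selects a filter whose nominal sigma is about
  `0.7·s`. The tests therefore pin the *internally consistent* contract —
  the suppression picks the dense argmax, and the selected size grows
  monotonically with blob size — rather than a nominal equality.
  Orientation uses Gaussian-weighted Haar responses in a radius-6-scale
  disc with a π/3 sliding sector; descriptors are 4×4 subregions of
  `(Σdx, Σ|dx|, Σdy, Σ|dy|)`, 64 values, unit-normalized.
* **MSER.** A union-find immersion builds the component tree of the 8-bit
  quantized image; the variation of a component is the one-sided relative
  area growth over `delta` gray levels, `psi(t) = (A(t+Δ) − A(t))/A(t)`,
  with `Δ = max(1, round(step% · 255))` and the threshold step interpreted
  as a percentage of the intensity range (0.3 % → 1 gray level). Regions
  are emitted at local minima of `psi` along their growth chain, subject
  to `psi ≤ 0.3` and areas within [100, 800] px²; nested emissions closer
  than 20 % in relative area keep only the more stable one. Both
  polarities are swept (the inverted image supplies bright-extremal
  regions). Each region carries its exact pixel set and a moments-based
  bounding ellipse.
* **FAST.** The 16-pixel Bresenham circle of radius 3; a corner requires
  `arc_length` contiguous circle pixels all brighter than `I(p)+T` or all
  darker than `I(p)−T`, with `T = 0.2` of the intensity range and the
  3-of-4 compass pretest applied when `arc_length ≥ 12` (where it is a
  necessary condition of the full test, so oracle equality is exact).
  A geometric caveat discovered during validation: a 90° axis-aligned
  corner subtends at most 11 contiguous circle pixels, so the default
  12-arc cannot fire on ideal square corners; the classical 9-arc variant
  is available through `detector_config(fast = list(arc_length = 9))` and
  is used in the square-corner recovery test. Corners are scored by the
  summed contrast margin, non-maximum suppressed in 3×3 with raster-order
  tie-breaks, and gated at `0.1 × max score`.
* **ORB.** FAST corners on a 1.2× image pyramid (8 levels), orientation
  from the intensity centroid `θ = atan2(m01, m10)` over a radius-15 disc,
  and 256 binary tests between pixels of a 5×5 box-smoothed patch, with
  the fixed pseudo-random test pattern rotated by `θ` and coordinates
  mapped back to level-0 pixels. The pattern is generated by a small
  deterministic LCG so it never touches R's RNG state. ORB runs FAST at a
  lower contrast threshold (0.08) — binary descriptors tolerate weaker
  corners and the benchmark expects ORB to produce the densest feature
  set.

## Matching and filtering

Matching is greedy mutual-best one-to-one: normalized cross-correlation
for real descriptors (higher is better), Hamming distance for binary ones
(lower is better), ties to the lower index. A strict-fidelity mode
(`metric = "ncc-all"`) applies NCC to binary descriptors treated as
floats. MSER regions and FAST corners carry no native descriptor, so they
are described with the 64-d real descriptor at the region's ellipse centre
(scale proportional to the equivalent circular radius) or the corner (at a
fixed nominal scale 2), which keeps all four detectors on one matching
path. No ratio test or score floor is applied by default — the epipolar
constraint is the outlier filter: in rectified mode a pair is an inlier
iff its absolute y-disparity is at most `epipolar_tol` (default 1 px);
general mode uses point-to-epipolar-line distances with `F`. Filtering
only flags; it never re-matches, and scores are untouched.

## Subpixel refinement

Integer-pixel detection quantizes image positions to ±0.5 px, which at
the default rig geometry (≈1 mm/px object resolution) corresponds to
roughly half a millimetre of triangulation error — it would dominate any
metric validation. `process_frame_pair()` therefore refines each matched
inlier before triangulation (config `refine = "centroid"`, default): the
rectified detection is mapped back through the inverse rectifying
homography into the *original, unresampled* image and iteratively
re-localized by an intensity-weighted centroid in a radius-6 window. The
border-ring mean is subtracted as the local background estimate, the
weights are squared (the centroid of a radially symmetric peak is
unchanged, while the clamp discontinuity at the rim is suppressed
quadratically), and a smooth radial taper centred on the running estimate
removes the asymmetry of a hard window edge. On rendered fiducials this
converges to ~1e-4 px; on generic texture features it re-localizes both
views to the same image-defined point, which is what makes the ray-miss
distance small. `refine = "none"` reverts to raw detection coordinates.

## The synthetic scene generator

No clinical stereo recordings of this kind are deposited anywhere, so the
generator is the package's validation instrument, and its design goal is
*exact end-to-end metric validation*, not photorealism.

* **Geometry.** Two converging pinhole cameras (defaults: baseline
  400 mm, focal length 1000 px, working distance 1000 mm, vergence 10°,
  640×480 frames). These are documented plausible stand-ins for a
  surgical stereo head; no clinical claim attaches to them. The surface
  is a Gaussian ridge (height 30 mm, width 45 mm — a spinous-process
  proxy) plus gentle large-scale undulation, over a ±140 mm domain on a
  dark background. Landmarks lie exactly on the surface; their image
  projections are computed analytically with `project()`, never estimated
  from the raster, so ground truth is exact to machine precision.
* **Appearance.** Lambertian shading with a mostly frontal light and a
  0.5 ambient floor, procedural albedo (band-limited speckle, RMS
  contrast 0.012, plus a handful of flat-top blobs sized for the MSER
  area window), global illumination scalar, additive Gaussian pixel noise
  in 8-bit gray levels, clipped to [0, 1]. Rendering is double precision.
* **Fiducial landmarks.** Each landmark is rendered as an analytically
  anti-aliased Gaussian spot (σ ≈ 1.1–2 px across views) on a locally
  uniform surround (flat within 10 px, blended out by 13 px), with its
  peak capped just below saturation. Three constraints drive this design:
  the refinement window (radius 6, corner distance 8.5 px) must see a
  uniform background for the centroid to be unbiased; the fiducial must
  survive CLAHE, which maps an isolated bright spot's contrast to
  essentially the *histogram population* between its surround and its
  peak — hence the dark base albedo (0.32), weak speckle and flat shading
  that concentrate each tile's histogram and let the clipped excess,
  redistributed uniformly over the spot's ~190-level span, carry the
  contrast; and the peak must not clip, because a saturated plateau
  biases the squared-weight centroid. Fiducial contrast and size vary per
  landmark and the descriptor window (which extends past the uniform
  surround into the texture) is what disambiguates otherwise similar
  spots during matching.
* **What passing tests do and do not show.** The generator demonstrates
  that the geometric chain — rectification, matching, epipolar filtering,
  subpixel refinement, midpoint triangulation — is exact to the micron
  scale when image localization is exact, and that the statistical
  machinery is correct. It does not emulate specularities, blood,
  retractors, occlusion, lens distortion or anatomical texture
  statistics, so test results do not predict clinical detection rates or
  clinical error magnitudes.

`planted_correspondence_set()` bypasses rendering entirely: exact
projections of random surface points, perturbed by isotropic Gaussian
pixel noise, with a chosen fraction displaced ≥ 50 px in y and labelled
as outliers — the fixture for matching/filtering and for the noise
calibration (500-point runs agree with a 50 000-point Monte-Carlo
reference within 20 %, and mean error is monotone over
σ ∈ {0, 0.25, 0.5, 1} px).

`make_textured_fixture()` builds the region-detector fixtures: hard-edged
ellipses on a background whose shading stays below the 8-bit quantization
step. The hard edges are deliberate: exact pixel-set invariance of
extremal regions under a *quantized* monotone intensity remap requires
regions separated from their surround by an empty intensity gap — with
soft edges, the selected threshold (and with it a one-pixel boundary
ring) becomes remap-dependent.

## Evaluation statistics

`summarize_runs()` mirrors a per-patient evaluation: group mean and SD
are computed over per-frame mean errors (a single-frame group reports
`NA` SD), medians and IQRs are pooled over per-feature errors with
type-7 quantiles (a documented convention — quantile conventions differ
at the margins), and inlier counts get max/min/mean/median/IQR across
frame pairs. Frames with zero inliers stay in the inlier statistics but
contribute no errors. `error_cdf()` pairs the empirical CDF with the
distribution-free Dvoretzky–Kiefer–Wolfowitz band,
`half_width = sqrt(log(2/α)/(2n))` (0.1358 at n = 100, 95 %), chosen over
a bootstrap for determinism and distribution-freeness. `timing_report()`
aggregates per-stage wall-clock times and derives frames-per-second from
the mean detection time; rectification, enhancement and segmentation are
booked under "preprocess".

## Numerical choices and degenerate inputs

* F scale: unit Frobenius norm, positive largest element.
* Near-parallel rays (`|sin| < 1e-8`), coincident camera centres,
  rank-3 F, epipoles inside the image, constant images at Otsu, empty
  foregrounds and sub-8-point estimation problems all raise explicit
  errors rather than returning unstable numbers.
* Tie-breaks are raster order (smaller y, then smaller x) in non-maximum
  suppression, lowest level at Otsu, lowest index in matching.
* All randomness is seed-controlled (`withr::with_seed`), and derived
  seeds stay within 32-bit integer range; identical seeds give
  byte-identical scenes, renders and outputs.

## Problem sizes

The shipped validation uses 640×480 synthetic frames with 20 landmarks,
500-point planted-correspondence sets against a 50 000-point Monte-Carlo
reference, 50 random 32×32 images for the FAST oracle, 100 for the Otsu
oracle, 20 textured fixtures for MSER invariance and five wedge fixtures
for the ORB rotation check — sizes chosen so each property is measured
with comfortable margins while a full validation pass stays in the
minutes range on a single core.

## Limitations

Lens distortion and bundle adjustment are out of scope (calibration is
taken as given); only two views are fused; matching has no ratio test, so
dense repetitive texture will produce outliers that only the epipolar
filter can catch; the detectors aim for algorithmic fidelity, not
bit-compatibility with any specific library implementation; and the
synthetic scenes, by design, understate the appearance variability of
real surgical imagery.
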