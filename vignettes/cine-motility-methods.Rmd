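---
title: "Quantifying gastrointestinal motility from cine MRI: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gastrointestinal motility from cine MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Free-breathing cine MRI of the abdomen shows the stomach and duodenum moving
in near real time (about 1.5 frames/s, 40 frames per plane at 0.656 s
intervals in the acquisition protocol this package targets). Two questions
are asked of such series: how fast does the stomach empty, and how active is
the duodenal wall? Both must be answered in the presence of respiratory
motion, and from wall outlines that are ultimately drawn by a human.

`cinemotility` implements that analysis as a pipeline of small, separately
testable stages, plus a digital phantom generator that renders scenes with
known kinematics so that every stage can be validated end to end without
patient data.

## Respiratory stabilization

Respiration moves the whole field of view by a few pixels, dominantly in the
cranio-caudal (y) direction. Between consecutive frames `n` and `n+1` the
shift `b` is estimated by exhaustively minimizing the mean squared intensity
difference over a region of interest chi:

    E(b) = sum_{x in chi} ( I_n(x) - I_{n+1}(x + b) )^2 / |chi|

over integer shifts in `[-r, +r]^2` (default `r = 10` px). Pairwise shifts
are accumulated, and frame `n` is translated by the negative of its
cumulative shift so the whole series aligns to frame 1.

Numerical choices:

* **Integer exhaustive search, no pyramid.** ROIs at this scale
  (~100 x 200 px, 40 frames) cost milliseconds, and exhaustive search is
  exactly testable against a brute-force oracle (the test suite does this on
  random instances).
* **Tie-breaking** among equal-energy minima: smallest shift magnitude
  first, then lexicographic (row, column). Degenerate inputs therefore
  favour the null shift; a zero-variance ROI returns `(0, 0)` with a
  degeneracy flag instead of an arbitrary argmin.
* **Vacated pixels** are filled with the frame's edge-median intensity and
  flagged in a validity mask. Filled pixels never enter any metric — all
  geometry downstream comes from contours, not intensities.
* **ROI indexing** is R-idiomatic 1-based inclusive
  `c(row_min, row_max, col_min, col_max)`; the contract is that the ROI
  keeps a margin of at least the search radius to every border, so every
  candidate shift is evaluated on fully valid pixels.
* Rotation, scaling and non-rigid deformation are deliberately out of
  scope: the stabilization target is whole-field translation only.

## Wall contours

Manual outlines are sparse: 20 seed points for the gastric fundus, 30 for
the duodenum. All geometry uses a standardized representation of the wall:
`n = 100` points at equal arc-length spacing on a periodic cubic
interpolating spline through the seeds, with arc length evaluated on a
20x-dense polyline of the spline. Orientation is normalized so the signed
(shoelace) area is positive; that makes the sign conventions of the velocity
decomposition well defined. The start point is the spline point nearest the
first seed.

Coordinates are physical millimetres throughout (origin at the top-left
pixel centre, x rightward, y downward, mm = 0-based pixel index x spacing),
so anisotropic pixel spacing is handled uniformly and contour files are
independent of raster resolution.

**Correspondence across frames.** The velocity decomposition treats point
`k` as the same material wall point in consecutive frames. After
stabilization, per-frame contours are matched by index, with the start index
of each contour chosen to minimize the summed squared distance to the
previous frame's points over cyclic shifts. This is the minimal rule
consistent with index correspondence; it does not track true material motion
tangentially (no imaging pipeline without markers can), which is why the
normal velocity component is the primary contractility readout.

**A known spline artifact.** A periodic interpolating cubic overshoots
sharp corners: through corner-plus-midpoint seeds of a square it adds about
1.7% arc length and bulges ~2-3% of the side length at the corners. Smooth
convex seeds (circles, ellipses, regular polygons) resample essentially
exactly (radius error < 0.05%, exactly convex output). Gut walls are smooth
at the seed densities used, so the corner case is documented rather than
worked around.

**Centroid** means the area centroid of the polygon (first moment of the
enclosed region), not the vertex mean — "centre of gravity of the area".

## Motility indices

For a per-frame area series `A(t)`, centroid series `G(t)` and frame
interval `dt = 0.656 s`:

* `DM(A) = 100 * sd(A) / mean(A)` (%), sample SD over the cine frames. The
  percent normalization makes the index size-invariant and is applied
  identically to fundus and duodenum.
* `DM(G) = sum_t |G(t+1) - G(t)|` (mm), the 2D path length of the centroid.
  The Y component is additionally exposed as the trace
  `DG_Y(t) = G_y(t) - G_y(0)` for figure parity, since published traces
  plot only Y. Whether the original in-house software summed 2D or Y-only
  displacements is not determinable; the 2D path length is the declared
  definition here.
* **Wall velocities.** For each frame pair and point `k`, the displacement
  divided by `dt` is projected onto the unit inward normal and unit
  counterclockwise tangent of the *later* frame's contour at `k`; inward
  and counterclockwise are positive. Because the frame is orthonormal the
  decomposition is exact: `V_N^2 + V_T^2` equals the squared speed
  (tested at 1e-9 relative).
* `DM(V_N)`, `DM(V_T)`: mean of `|V_N|` (resp. `|V_T|`) over all frame
  pairs and points, in mm/s. Absolute values prevent simultaneous
  contraction and relaxation from cancelling. The mean (not the sum) is
  used so the index is independent of the number of wall points and frames
  and lands on the published magnitude scale (~0.2-2 mm/s); this
  aggregation was a genuinely open choice and is flagged as such.
* **Gastric residual volume index**: per scan (MS1, MS2, MS3), the sum over
  designated coronal planes (P1-P4 by default) of the frame-mean fundus
  area, expressed as a percentage of MS1. MS1 is exactly 100 by
  construction. Because only the MS1-normalized ratio is ever used, slice
  thickness never enters and the index stays in area units internally.
* **Paired comparisons** between conditions use the classical two-sided
  paired t-test matched by subject (`stats::t.test`); all-zero differences
  return `p = 1` with a degeneracy flag rather than an error. P values are
  reported unadjusted, and responder-style subgroup analyses are explicit
  user input — automating a selection made post hoc by observed effect
  direction would embed a circular rule.

## The digital phantom

No imaging data accompany the analysis this package implements, so the
generator is a first-class module, not a test fixture. It emulates:

* **Fundus**: a bright ellipse whose area follows
  `baseline * (1 - emptying) * (1 + a * sin(2 pi t / T))` — a slow
  pacemaker-like oscillation (default amplitude 5%, period 20 s, i.e.
  ~3 cycles/min) within scans, and stepwise emptying between scans
  (MS1 -> MS2 -> MS3), mirroring the two time scales of the real study.
* **Duodenum**: a C-shaped tube of resting radius `r0` around a spline
  centerline; peristalsis is a Gaussian-profile contraction ring
  (`r(s, t) = r0 (1 - depth * g(s - c(t)))`) travelling at a set speed and
  recurring with a set period, amplitude-tapered near the tube ends so the
  end caps stay static.
* **Respiration**: whole-frame translation by a rounded sinusoid (integer
  pixels). Integer injection is what makes "exact recovery" a meaningful
  test of the integer-search stabilizer; sub-pixel breathing would add a
  bounded half-pixel floor to every recovery test without changing any
  conclusion.
* **Noise**: additive Gaussian, SD expressed as a fraction of the dynamic
  range, applied after the respiratory shift.

Rendering uses 4x supersampled binary occupancy averaged to gray, giving
soft partial-volume-like edges; an intensity-integral area estimate
converges to the ground-truth polygon area as pixel spacing shrinks (tested
at two resolutions).

**Ground truth.** Boundary polygons, areas and centroids are stored per
frame in anatomy coordinates. For the duodenum, wall points sit at fixed
centerline arc positions and move only along the centerline normal, so the
ground-truth velocities are `V_N = -dr/dt` (finite-differenced over the
frame interval, i.e. the radius-field derivative at the sampling the
pipeline sees) and `V_T = 0` identically; the ground-truth `DM(V_N)` is the
arc-length-weighted mean of `|V_N|`. Seeds handed to the pipeline are
equally spaced ground-truth boundary points in *raw* image coordinates
(respiration included) — what an observer would mark on unstabilized
frames — so the stabilization stage is genuinely exercised.

**The synthetic study.** Eight subjects x two conditions x three scans,
each scan four fundus planes plus one duodenum plane. The treated
condition's MS3 emptying averages 27% vs 16% untreated (residuals 73% vs
84%), with a shared subject effect of SD 11.5 percentage points and
condition-specific noise of SD 7 points. This split reproduces both the
published per-condition spread (~13-15 points) and the paired-difference
spread (~10 points) implied by the reported paired t-test at n = 8; ring
depth averages 0.55 vs 0.12 so the treated condition's wall velocities are
several-fold higher, as observed. These are the generator's fixed study
conditions, not tuning knobs.

## What the phantom does and does not show

Passing tests on the phantom demonstrate that the *measurement chain* —
stabilization, resampling, correspondence, projection, normalization,
paired testing — recovers known kinematics at the stated tolerances. They
do not validate manual outlining accuracy on real tissue contrast, non-rigid
respiratory deformation, through-plane motion of the duodenum, susceptibility
or flow artifacts, or observer variability: the phantom's seeds are exact
boundary points, so contour error in practice is bounded below by the human,
not by this code. The tangential index `DM(V_T)` additionally absorbs
correspondence slippage where the wall deforms, and should be read as a
lower-fidelity companion to `DM(V_N)`.

## Problem sizes and reproducibility

All randomness flows from explicit seeds; phantom and study regeneration is
bit-reproducible, and the pipeline is deterministic given inputs and
configuration. The test suite and the acceptance script run the phantoms at
reduced rasters (48-80 px grids, 4-20 frames) and the study generator at
2-3 subjects for rendered runs — the indices are computed from mm-space
contours, so the raster choice affects only the stabilization stage, which
is separately validated at its own scale. Statistical operating
characteristics (power at the design effect, size under the null) are
estimated on the generator's ground-truth residuals over 50-200 replicate
parameter draws of the full n = 8 design.

## Known limitations

* Translation-only stabilization; integer-pixel resolution.
* DICOM is not read directly; stacks are multi-page TIFF with a plain-text
  sidecar (`pixel_spacing_x/y`, `frame_interval`, `plane_id`, `scan_id`).
  Pixel spacing is always external metadata — never inferred from image
  content — because acquisition matrices and fields of view do not
  determine the reconstructed spacing.
* Per-frame seeds are required inputs; there is no automatic wall
  segmentation and no propagation of a single outline.
* No frequency-domain analysis of the pacemaker rhythm, and no
  transport/mixing metrics: the indices quantify wall motion, not the
  physiological quality of the resulting flow.
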