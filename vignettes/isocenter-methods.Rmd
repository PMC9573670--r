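---
title: "Isocenter determination from gel-dosimeter CBCT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isocenter determination from gel-dosimeter CBCT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelshot)
```

## The measurement

A linac's radiation isocenter is verified by firing several narrow slit
beams (star shot) or a non-coplanar beam set through a polymer-gel
dosimeter in a cylindrical container. Radiation-induced polymerisation
raises the local CT density, so a kilovoltage CBCT or iCBCT scan of the
gel shows the beam tracks as bright slabs. The isocenter estimate is the
centre of the smallest circle (2D) or sphere (3D) touching every
reconstructed beam axis; its distance to a fiducial-defined reference
point is the reported offset. `gelshot` implements the whole chain —
volume I/O, preprocessing, track detection, geometric fitting, QA
metrics — plus a synthetic phantom generator that provides ground truth
for every stage.

## Coordinate frame

All geometry is in mm in a right-handed frame: x lateral (+x to the
right when facing the gantry), y along the couch toward the gantry, z
vertical up. A `ct_volume` maps array index (slice i, row j, col k) to
`origin + (k*sx, j*sy, i*sz)` with voxel centres carrying positions. The
beam central-axis direction is `d(gantry g, couch c) = Rz(-c) (sin g, 0,
-cos g)`: gantry 0 fires straight down, and the collimator angle rotates
the slit about the axis without changing the direction. The container
lies with its long axis along y (the gantry rotation axis), so the
coplanar star-shot pattern lives in a plane of constant y; its in-plane
coordinates are (u, v) = (x, z). The analysis plane is the mean over a
thin slab (default 5 slices) centred at the fiducial-marker plane.
Background and irradiated scans of the same container in place are
treated as exactly registered (same `frame_id`); no image registration
is performed.

## The synthetic phantom

`phantom_spec()` + `simulate_phantom()` emulate the study conditions:

* **Container** — gel cylinder (default inner diameter 90 mm, the main
  container; 80 mm for the smaller one) with a 3 mm wall in air
  (−1000 HU). Gel sits near +15 HU, the wall at +100 HU.
* **Noise** — i.i.d. white Gaussian HU noise whose Std is the measured
  per-mode VOI noise (`noise_presets()`); the default 1.555 HU is the
  TrueBeam iCBCT Pelvis mode, the optimum found for this readout. Mode
  realism comes *only* from this Std: there is no projection-domain
  simulation, no noise correlation, and no spatially varying noise.
* **Beam hardening** — a radially symmetric offset
  `A (1 - (r/R)^2)` with A = −20 HU by default, deepest on the container
  axis, reproducing the inverted-parabola cupping of an air-scanned
  cylinder. Optional concentric rings (`ring_amp_hu`, sinusoidal in r)
  emulate ring artifacts.
* **Tracks** — each beam contributes
  `dose_to_hu(dose) * S(t1; gap) * S(t2; length)` where S is an
  erf-edged box profile with penumbra sigma 0.5 mm (sub-voxel smoothness
  is needed for stable line fitting; no published value exists). The MLC
  gap is widened in quadrature by `leak_mm` = 0.5 mm so a closed (0 mm)
  gap still leaves a faint visible zone, as observed. The dose response
  is piecewise linear: slope 2.5 HU/Gy to 18 Gy, a reduced-slope ramp to
  a +60 HU plateau at 40 Gy, constant beyond; with 1 Gy per 100 MU the
  standard 10,000 MU irradiation is fully saturated at +60 HU. Absolute
  track amplitude in HU is not published for this gel, so it is a free
  parameter; only the relative amplitude matters for geometry, and the
  post-irradiation signal growth ("post-effect") is reduced to this
  amplitude scale.
* **Markers** — three bright spheres (default +500 HU, radius 1.5 mm) on
  the container surface at the 0/90/270-degree positions in the plane
  y = −1 mm, mimicking the copper-wire dots that proved artifact-free.
  Spheres are rendered with an anti-aliased rim (half-voxel linear ramp)
  so that no voxel sits knife-edge on the boundary.
* **Scatter** — `beam_scatter_mm` displaces each axis perpendicular to
  itself by a seeded random amount up to the bound, for studying how the
  fitted radius tracks true beam spread.

Everything is seeded: the same spec and seed give bit-identical volumes.
The generator also returns the noiseless background and track fields and
the exact axes, which the test-suite oracles consume.

Default grids are 0.9 mm in-plane with 2 mm slices (the clinical
export), covering a 108 mm transversal field of view and 40 mm axially
for star-shot work; 3D beam sets should be simulated with an 80 mm axial
field of view so that beams running near the couch axis have enough
clean track length on either side of the crossing region.

What passing tests on this phantom do **not** show: robustness to
reconstruction-specific texture, scatter/cupping beyond the radial
parabola, metal streaks, couch sag or true setup error, or gel
inhomogeneity. The simulator is a geometry-and-noise testbed, not a
physics simulation.

## Preprocessing

`average_series()` is the voxelwise mean; averaging n series shrinks the
VOI Std like 1/sqrt(n) (verified property). `subtract_background()`
removes everything common to both scans — container, hardening parabola,
rings — leaving the track increments.

The filter bank (`filter_spec()` / `apply_filter()`) reproduces the
menu of a gel-dosimetry workstation: mean, median, adaptive mean,
adaptive median, Kuwahara, FFT window (12 named windows), Savitzky–Golay
and envelope. Decisions where the original implementations are
unpublished:

* **Envelope** — upper envelope = grayscale dilation, lower = erosion,
  both with a square structuring element of the stated kernel; output =
  per-voxel midpoint (selectable `inner_stat`), iterated. This honours
  the known parameter list (mean, 3 iterations, kernel 3, 2D) and gives
  smoothing that respects edges; it is logged as an approximation.
* **Adaptive mean** — Lee-style local-variance gain
  `m + max(v - v_n, 0)/v * (x - m)` with the noise variance estimated as
  the median local variance unless supplied.
* **FFT windows** — hann, hamming, blackman, nuttall, blackman–nuttall,
  blackman–harris, flat-top, bartlett, welch, cosine, tukey (alpha 0.5)
  and rectangular, applied as a separable frequency-domain
  multiplication per slice (or per volume in 3D mode).
* **Edges** — reflect padding for all kernels (avoids rim artifacts
  inside the container); Savitzky–Golay instead uses the projection
  matrix's leading/trailing rows at the ends so polynomials up to the
  fitted order pass through unchanged everywhere.

Linear filters (mean, FFT window, Savitzky–Golay) commute with
subtraction, which is why filtering must be applied to background and
irradiated images symmetrically: filtering only one side leaves
structured residues (ring artifacts) in the difference. The pipeline
defaults to symmetric filtering and logs a warning when asked to filter
one side only. The recommended protocol needs no filter at all.

## Track detection

**2D star shot.** Working on the background-subtracted star plane, a
weighted sinogram sweep (0.25-degree steps; planned angles restricted to
hint ± 3 degrees when available) finds the track angles — a track
parallel to the projection rays gives the sharpest peak, with ties
broken by prominence then smaller angle. Each track's offset starts at
the intensity-weighted centroid of its projection peak and is refined by
intensity-weighted orthogonal regression (2D PCA) over a ribbon of
±3 gap widths around the line, excluding a 5 mm disk around the
preliminary crossing point and ±1.25 gap widths around every other line
(beams overlap there and would bias the fit). On the clean phantom this
recovers angles to ~0.01 degrees and offsets to a few microns; the
suite requires 0.2 degrees / 0.05 mm noiseless and 0.25 mm at the
iCBCT-Pelvis noise level.

**3D.** Candidate voxels are those above 5 robust (MAD-based) noise
Stds, floored at 2% of the volume maximum so a noise-free volume does
not admit far penumbra tails. Candidates are assigned to the nearest
planned axis through the coarse intensity centroid; each axis is then
re-estimated as the weighted principal axis of its ribbon (±2 gaps),
iterated until the axis moves by less than 0.01 mm / 0.01 degrees (at
most 10 iterations). Two trimming rules keep the PCA unbiased: voxels
within 1.5 gaps of another beam's axis are excluded, and the ribbon is
sliced into slabs along the axis with any slab dropped that either
touches an exclusion region or is an end slab — an obliquely clipped or
partially excluded slab has an off-axis centroid that would tilt the
axis (the clipped solid is effectively sheared).

**Markers.** The brightest blob at the container rim within a
±25-degree window around each expected angle, near the requested
transversal plane, localised by intensity-weighted centroid. The
reference point is the intersection of the line through the 90- and
270-degree markers with the perpendicular through the 0-degree marker —
one reasonable reading of a construction that is not published in
algorithmic form — and a user-supplied reference always overrides it.

## Isocenter fitting

The reported centre is the Chebyshev point: `argmin_x max_i dist_i(x)`.

* **2D** — with normal-form lines, the problem is the linear program
  minimise r subject to `-r <= a_i u + b_i v - c_i <= r`. With the
  handful of beams a star shot uses, the LP is solved exactly by
  enumerating all triples of active constraints (every bounded
  3-variable LP optimum is basic) and keeping the feasible solution with
  the smallest r.
* **3D** — the least-squares centre comes from the closed-form normal
  equations `sum_i (I - d_i d_i')(x - p_i) = 0`; the minimax centre is
  found by Nelder–Mead restarts seeded there, polished by a 26-direction
  pattern search down to 1e-9 mm steps (the objective is convex but
  non-smooth at the optimum). Test oracles (brute-force grids, simplex
  search, and line bundles constructed tangent to a known sphere with
  positively spanning contact normals) agree to 1e-4 mm.

Both fits report the min–max radius, per-beam distances, the
least-squares centre for transparency, the offset vector and distance
to the reference point, and two verdicts: radius against the 1 mm
star-shot tolerance (TG-142) and offset against the 0.5 mm
machine-performance-check style threshold. The offset vector is
reported so either a full 3D distance or an in-plane distance can be
recovered; note that with markers in the y = −1 mm plane and the beam
crossing at y = 0 the 3D offset includes that 1 mm axial separation by
construction.

## QA metrics

`voi_stats()` computes mean/Std over voxels whose centres lie in a
cylindrical VOI (sample Std). `uniformity_ipa()` is the
installation-product-acceptance arithmetic: each peripheral VOI mean
(left/top/right/bottom) minus the centre mean, their per-series mean,
and the across-series mean, all exact on the inputs with ±30 HU
verdicts; rounding (2 dp, halves away from zero, matching the published
tables) is display-only. When re-deriving published table cells from
their printed five positional means, agreement is to one unit in the
last printed decimal: the printed inputs are themselves rounded, so a
recomputed difference can legitimately sit 0.01 from the printed one.
The peripheral VOI offset is 0.8 of the module radius by default
(configurable; the exact published offset is not printed, so published
rows are reproduced from their printed means, not by re-segmentation).

`schedule_scans()` encodes the tube-heating rules: TrueBeam sustains up
to five consecutive scans with no gap; Halcyon only two, after which
every further scan needs 5 min (Pelvis) or ~6 min (Pelvis Large) of
cooling. The underlying tube-temperature percentages are documented
rationale; the scheduler encodes the resulting rules, not a thermal
model. More than five scans is outside the validated range and returns
a warning verdict.

## Problem sizes and numerical choices

The test suite simulates the 80 mm container at 1 mm in-plane / 2 mm
axial spacing for repeated runs (about 120k voxels per volume) and the
full 90 mm container at 0.9 mm for end-to-end checks; stochastic
properties use 10–20 seeds per condition. These sizes were chosen so the
whole suite exercises every stage, including 100-instance geometric
oracle sweeps and a 10 x 10 scatter-monotonicity grid, in a few minutes
on one CPU. Degenerate inputs fail loudly with typed conditions:
all-parallel line sets, coincident planned directions, VOIs or profile
endpoints outside the volume, non-uniform DICOM slice gaps (beyond 1%),
mixed series UIDs, and missing rescale tags.

## Known limitations

* White, uncorrelated noise understates the structured texture of real
  iCBCT reconstructions; detection margins on real scans will be
  narrower than the micron-level recovery seen on the phantom.
* The envelope and adaptive filters are reasonable reconstructions of
  unpublished commercial algorithms, not replicas.
* The absolute HU amplitude of irradiated gel tracks is a free
  parameter; geometry is insensitive to it, but contrast-based claims
  are out of scope.
* The DICOM reader supports uncompressed little-endian single-frame CT
  with axis-aligned orientation — what the fixture writer emits and
  anonymised linac exports typically contain — not enhanced multi-frame
  objects.
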