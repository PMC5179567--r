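---
title: "Methods: phantom-validated analysis of longitudinal retinal imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom-validated analysis of longitudinal retinal imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinaivm)
```

## The measurement problem

Longitudinal intravital two-photon microscopy of the mouse retina images
the same eye repeatedly over the course of experimental autoimmune
uveoretinitis: 300 µm z-stacks over a 1400 µm × 1400 µm field, one stack
per minute for 20 minutes per visit, at days 7, 11, 14, 21 and 28 after
immunization. Three detection bands (466 ± 20, 525 ± 25, 593 ± 20 nm)
carry, depending on the mouse line, labeled immune cells, vessel labels,
retinol autofluorescence from the retinal pigment epithelium, and the
donor/acceptor emission of a troponin-based FRET calcium sensor expressed
in ganglion-layer neurons. The optic nerve head (ONH) and the vessels do
not fluoresce and appear as shadows; the ONH anchors a radial coordinate
system for all spatial statistics.

This package turns those stacks into three families of quantities: zonal
infiltration counts around the ONH, per-track motility and signed radial
displacement statistics, and calibrated neuronal calcium maps with a
dysfunction threshold. Because no image data for this protocol are
publicly deposited, the package also contains a synthetic phantom of the
whole acquisition with known ground truth; every downstream claim the test
suite makes is checked against that ground truth.

## The phantom: what it emulates, and what it does not

`phantom_config()` parameterizes a flat-slab retina:

* **Static anatomy.** A non-fluorescent ONH disc (default radius 100 µm at
  the field centre) and straight vessel stripes radiating from it (default
  6 vessels, 20 µm wide) multiply all tissue signals by a shadow mask; the
  vessel-label channel is bright exactly along the stripes, emulating
  dextrane/rhodamine labeling. The bottom z-slices carry a uniform
  autofluorescent background (the pigment epithelium) in the 525 nm band.
* **Cells.** Each session day seeds an independent cohort (cell identity
  is deliberately *not* preserved across days — only within-session motion
  is tracked). Radial seeding distance from the ONH is gamma-distributed
  with shape 2 and a per-day scale: one knob moves the population from
  ONH-concentrated (early disease, scale ≈ 100 µm) to peripherally spread
  (late, scale ≈ 250 µm), reproducing the outward-spreading infiltration
  pattern. Seeds are re-drawn until all pairwise distances exceed
  `min_separation_um` (default 40 µm), making cells separable — the
  detector does not split touching objects, so the phantom must not create
  them. Within a session a motile cell (probability `motile_fraction`)
  steps by `drift_rate_um_min · Δt` along the current radial unit vector
  plus isotropic Gaussian noise `step_sigma · sqrt(Δt)` per axis; sessile
  cells receive the noise only. Positions are clipped at the field edge
  and flagged `exited`; exited frames are excluded from motility metrics.
  Cells render as 3D Gaussian blobs (lateral σ = 6 µm, a lymphocyte-scale
  soma; axial σ = 15 µm, matching the axial point-spread extent of
  long-working-distance water immersion optics).
* **Calcium and FRET channels.** The ganglion-layer calcium field is a 2D
  grid: 100 nM baseline (the sensor's resting readout), optional lesion
  discs of arbitrary concentration, and an ionomycin preset that sets the
  whole field to 3 µM (the saturating positive control). The field maps to
  a FRET ratio through the anchored Hill calibration and splits the
  sensor's total corrected intensity into donor (466) and acceptor
  (525/593, 60/40) channels. Raw intensities invert the correction chain —
  multiply by η/α and add the per-channel background I_B — so that
  applying the forward correction recovers the intended signal exactly;
  with smoothing disabled this round trip is exact to floating point, the
  property the calcium-recovery tests rely on.
* **Noise.** Poisson noise on expected photon counts at `photon_scale`
  photons per intensity unit (SNR of a structure of intensity I is
  sqrt(I·photon_scale)); `Inf` disables noise. There is no detector read
  noise — it is not characterized for this setup — and no optical PSF
  blur, aberration, eye curvature, bleaching, or within-stack motion.
  Consequences: passing tests demonstrate the correctness of the
  *algorithms* under known geometry and shot noise, not robustness to
  optical blur, curvature-induced distortion, or drift during a stack.

Determinism is a contract: every stochastic step draws from an RNG stream
seeded from `rng_seed` (plus fixed per-day offsets), and the caller's RNG
state is restored, so identical configurations reproduce bit-identical
phantoms. The default test fixture is the small preset
(`small_phantom_config()`: 256 × 256 × 10 voxels over the full physical
volume); the full 994 × 994 acquisition grid remains reachable through
`phantom_config()`.

## Channel correction and the FRET ratio

Each acquisition band c ∈ {466, 525, 593} is corrected as

> corrected = (α_c / η_c) · G_σ( max(I_c − I_B,c, 0) )

i.e. background subtraction with clamping at zero, Gaussian smoothing of
each x–y plane (normalized kernel truncated at 4σ, replicate borders, no
smoothing along z because voxels are strongly anisotropic), then a fixed
per-channel gain. The detector sensitivities η, overlap coefficients α and
backgrounds I_B are instrument constants that must come from
configuration; defaults are 1, 1 and 0. Whether α and η multiply or
divide is a pure gain convention: the implementation fixes
k_c = α_c/η_c as the per-channel gain, and since any fixed positive gain
rescales the corrected channels monotonically, the ordering of the FRET
ratio — and hence every threshold decision — does not depend on the
convention. The donor (466 nm) channel uses α = 1 by default, since
spectral overlap is a donor-bleed phenomenon affecting the acceptor bands.

The relative acceptor FRET ratio is computed voxelwise as
(c₅₂₅ + c₅₉₃)/(c₅₂₅ + c₅₉₃ + c₄₆₆). Voxels whose denominator falls below
1e-6 of the image's maximum denominator (vessel shadows, the ONH, any
unlabeled tissue) are *undefined*, not zero: a 0/0 ratio is noise, and
zero-filling would masquerade as a strong calcium depression. The default
neuronal mask is an Otsu threshold on the time-averaged donor + acceptor
sum, which selects sensor-expressing tissue.

## Anchored Hill calibration

The sensor's two characteristic points — a 47 % ratio at 1 µM free calcium
and a 70 % ratio at 3 µM under ionomycin — are the only quantitative
anchors available, and two points cannot determine a four-parameter
sigmoid. The package therefore fixes the asymptotes (R_min = 0.25,
R_max = 0.85, both configurable; chosen to bracket the working range
0.26–0.70 with comfortable margins on either side) and solves the Hill
form exactly through both anchors in closed form:
y_i = (R_i − R_min)/(R_max − R_i), n = log(y₂/y₁)/log(C₂/C₁),
K_d = C₁/y₁^(1/n). With the defaults this gives K_d ≈ 1.44 µM and
n ≈ 1.50. The forward and inverse maps are exact algebraic inverses
(round-trip error at machine precision); ratios at or below R_min map to
concentration 0 with a `floor` flag, at or above R_max to `Inf` with a
`saturated` flag, so saturated voxels still count as above any finite
dysfunction threshold. The baseline readout of 100 nM corresponds to a
ratio of 0.261, comfortably below the 0.47 dysfunction boundary.

The dysfunction fraction asks for *sustained* elevation: a masked voxel
counts only if its inferred calcium stays at or above the threshold
(default 1 µM) for at least `persistence_frames` consecutive frames —
by default the entire session, operationalizing "sustained within the
20-minute imaging window". Cross-session persistence is a per-day report,
not an accumulation, because sessions are days apart.

## Detection, zones, and counting

Detection thresholds voxels (fixed value or per-frame Otsu), groups them
by 26-connectivity in 3D, discards components outside a volume window
(defaults 65–4200 µm³, bracketing single lymphocyte-to-phagocyte somata;
the phantom tests pass explicit ranges because voxel volumes on coarse
test grids are far from the full-resolution defaults), and reports
intensity-weighted centroids in micrometres — all distances and volumes
are computed in physical units so anisotropic z-sampling cannot distort
them. An optional `refine = "gaussian"` mode interpolates the log
intensity quadratically about the brightest voxel of each component,
which recovers the centre of an isolated Gaussian blob exactly in the
noise-free limit; the ground-truth count comparisons use it because a
boundary-straddling centroid error of even half a micrometre can move a
cell across a zone radius.

Zones are half-open annuli: zone k holds radii in [r_{k−1}, r_k), so a
cell exactly on a boundary belongs to the outer annulus. The default
radii 226/452/678 µm follow the per-radius zone definition; a variant
with radii 215/430/625 µm (equivalently, diameters 430/860/1250 µm) is
reachable through configuration. Session counts use the first frame by
default — a moving cell must not be counted once per frame — with a
per-frame mean available as an option.

## Tracking and radial statistics

Frame-to-frame linking solves a global one-to-one assignment minimizing
total squared planar distance, with links beyond `max_link_distance`
forbidden and a cost of `max_link_distance²` for each unlinked track end
or unlinked new detection. This is the standard augmented-matrix
linear-assignment formulation of particle linking; the solver is an
O(n³) shortest-augmenting-path implementation with dual potentials,
validated in the suite against exhaustive enumeration of all partial
matchings on instances with up to 6 detections per frame. Because any
allowed link (cost ≤ D²) is cheaper than terminating plus re-birthing
(2D²), gating is the only mechanism that breaks tracks. Ties between
equal-cost optima are resolved deterministically by the solver's fixed
scan order over sorted inputs. There is no gap closing: a missed
detection terminates a track, the simplest behaviour consistent with the
phantom's separable cells, and tracks shorter than `min_length` frames
(default 5) are discarded as unreliable.

All motility metrics are planar (x–y). Axial sampling (15 µm steps) is an
order of magnitude coarser than lateral sampling, so including z would
add quantization noise without information; trajectories are reported in
the imaging plane. Degenerate single-point tracks yield zero metrics and
a flag rather than NaNs.

The signed radial displacement of a track is implemented as the
difference of end-point and start-point distances to the ONH. The
equivalent construction via ONH-to-start and ONH-to-end vectors projected
on the radial direction gives the same sign semantics — positive
centrifugal, negative centripetal — and the distance-difference form is
manifestly invariant under rotations about the ONH and under joint
translations, properties the suite asserts. The global displacement
vector sums radial displacements over motile tracks (net displacement
strictly greater than 10 µm per 20-minute session; 20 µm is the
convention for trajectory overlay plots). Whether such sums should pool
cells per session or per condition is left to the caller, who passes an
explicit track selection.

## Registration and ONH localization

Repeated visits are aligned by a rigid x–y translation that maximizes the
cross-correlation of time-averaged, z-projected vessel channels (FFT
cross-correlation, integer-pixel peak, vacated pixels zero-filled).
Rotation is not estimated: repositioning with a head-post is
translational to ~10 µm, and the vessel tree leaves too little rotational
signal at these fields of view; rotational misalignment is an open
limitation. A registration is flagged uncertain when the correlation peak
is less than 1.2× the best peak outside its 5 × 5 neighbourhood — a
vessel-free or structureless image warns rather than fails.

The ONH is localized on the autofluorescence channel as the centroid of
the largest dark connected region, where "dark" means at or below the 5th
intensity percentile *and* below half the median (so a flat image has no
shadow and raises a localization error instead of returning its centre).
The dark mask is first eroded by 15 µm to detach the thin vessel shadows
that radiate from the disc and would otherwise drag the centroid; a
manual override is accepted and returned verbatim.

## Group statistics

`compare_groups()` runs a one-way ANOVA across groups and all pairwise
two-sample t tests using the pooled residual standard deviation, with
Bonferroni adjustment applied literally — each raw p multiplied by the
number of pairwise comparisons and capped at 1 — and stars at p < 0.05,
0.01, 0.001. Groups with fewer than two values are excluded with a
warning. The units of replication (cells versus animals) are the
caller's choice: passing per-cell values across conditions
pseudoreplicates if cells from one animal are correlated, so per-animal
summaries are the safer input when animals are the inferential unit.

## Numerical and design choices, in brief

* Coordinates: 0-based voxel grids with pixel centres at
  (index − ½)·pitch; physical micrometres with origin at the image
  corner; radial analyses re-origin at the ONH.
* Sessions store as multi-page 32-bit float TIFF (channel fastest, then
  z, then time) with a JSON metadata sidecar; intensities are scaled into
  [0, 1] for storage and restored on read, so round trips are exact to
  float32 (~1e-7 relative), which every comparison involving file IO
  tolerates explicitly.
* Smoothing kernels are normalized and truncated at 4σ with replicate
  borders: total intensity is preserved to well under 0.5 % away from
  borders.
* Otsu thresholds use a 256-bin histogram between the data extremes.
* The FRET denominator floor, the strict motile inequality, the
  outer-annulus boundary rule, and the exact-anchor calibration are all
  asserted by tests at the tolerances stated in their descriptions.
* Test and acceptance problem sizes: phantoms of 96–256 pixels laterally
  and 4–10 z-slices over the full physical field, 2–21 frames, 5–50 cells
  per session; 100 seeded phantoms for sign recovery; 1000 random
  instances for the linking oracle. These sizes were chosen so the full
  suite exercises every code path on a laptop-scale machine while leaving
  statistical margins (3 standard errors) that do not depend on the seed.
* The sign-recovery and drift-magnitude experiments feed ground-truth
  positions to the tracker, isolating the linking and radial statistics
  from segmentation; detection accuracy is certified separately by the
  recall/precision and zone-count tests.

## Known limitations

The phantom's kinetics are illustrative, not fitted: no quantitative
infiltration-rate law exists to calibrate them, so per-day cell counts
and seeding scales are plausibility choices, and conclusions about *rates*
of infiltration transfer to real data only qualitatively. Touching cells
are not split; real clustered infiltrates (e.g. dense ONH aggregates at
disease onset) would be under-counted. Rotational misalignment,
within-stack motion, optical blur and eye curvature are not modeled or
corrected. The Hill asymptotes R_min/R_max are engineering defaults, not
sensor measurements; all threshold-crossing statistics are, by
construction, insensitive to their exact values near the anchored range,
but absolute concentrations far outside 1–3 µM extrapolate the curve.
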