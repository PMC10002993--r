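---
title: "Method agreement for DBS electrode reconstruction: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Method agreement for DBS electrode reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models behind `dbsreco`, the conventions it
enforces, and the design decisions taken where the underlying procedures are
genuinely open — in the spirit of a methods section, so that a user can judge
what a passing test suite does and does not demonstrate.

## Coordinate frame and hemisphere conventions

All stereotactic coordinates are stored in a single physical AC–PC frame:
origin at the posterior commissure, +Y the unit vector from PC to the anterior
commissure, +Z inferior (perpendicular to +Y within the midsagittal plane),
+X right-lateral completing a right-handed triple once the inferior +Z is
accounted for (`x = y × (−z)`). `acpc_frame()` builds this frame from three
landmark points; the midsagittal point must lie superior to the AC–PC line,
and collinearity is rejected when the sine of the angle between the
midsagittal offset and the AC–PC line falls below 1e−6. `to_acpc()` /
`from_acpc()` are rigid (rotation + translation), so all distances are
frame-independent to 1e−9 mm.

Two conventions matter when hemispheres are combined:

* **Display convention.** Published coordinate tables print left-hemisphere
  rows with every axis negative. With storage in one physical frame (left X is
  negative, but anterior Y and inferior Z carry the same sign on both sides),
  this display transform is `(x, −y, −z)` for left rows — equivalently, a
  negation of all three axes of the right-mirrored representation. It is
  applied only at reporting time; stored geometry is never touched.
* **Magnitude pooling.** "All electrodes" samples pool per-axis coordinate
  *magnitudes* (`abs()` per axis), folding the mirrored hemispheres together.
  Paired tests and mean discrepancies are computed on these magnitudes for
  every scope; for a single-hemisphere scope this equals a global sign flip of
  the display values, so p-values are unaffected, while discrepancies keep the
  orientation in which published left-row discrepancies are expressed
  (e.g. printed means −12.11 vs −11.82 give a discrepancy of −0.29, the
  difference of magnitudes).

## Electrode model

A quadripolar lead is modeled as a straight line through the center of the
ventral-most contact and a second point marked on the cranial, bend-free part
of the electrode; lead bending below that segment is deliberately ignored, as
the cranial contact-bearing span is the part least affected by bending.
Contact *i* (0-based, ventral first) lies `i × 2 mm` up the trajectory. The
per-coordinate distance equations
`x_i = x_1 ± sqrt(l_i² − (y_1−y_i)² − (z_1−z_i)²)` (and cyclic permutations)
are satisfied by this parametric form; the sign ambiguity in the printed
radical form is resolved by always stepping toward the cranial point, because
contacts are dorsal to the ventral-most contact by hardware definition.

The physical tip lies `tip_to_contact + contact_length/2 = 1.5 + 0.75 =
2.25 mm` ventral of the ventral contact *center*: manufacturer constants give
the 1.5 mm tip-to-contact-edge gap, and marked coordinates are contact
centers, hence the half-contact. Both constants are data (`electrode_spec()`),
so other lead geometries can be configured; Medtronic 3389 and PINS 301 ship
as built-ins with identical constants. MER depth comparisons use this tip
point, since the intraoperative drive records depth of the tip, not of a
contact center.

## Relative position at the maximum red-nucleus level

The construction anchors on the axial level where the RN cross-section is
largest:

1. `max_rn_level()` scans the mesh's z-extent at `slice_step = 0.1 mm`
   (an order of magnitude below the ~1 mm effects of interest; the located
   level is exact to one step by construction) and returns the level of
   maximal cross-sectional area, first level on ties.
2. Cross-sections are **exact mesh–plane polygons**, not voxel masks: every
   crossing triangle contributes a segment, computed once per undirected mesh
   edge and chained by edge identity, so polygon closure is immune to
   floating-point endpoint matching; area and centroid come from the shoelace
   formulas, area-weighted over multiple loops. Vertices falling numerically
   on the plane are perturbed by an infinitesimal deterministic epsilon.
3. The electrode's center point at the level is the intersection of the
   contact span (segment from ventral-most to dorsal-most contact center —
   the span is *not* extrapolated) with the plane; electrodes whose span does
   not reach the level are flagged `above_rn_level` and excluded listwise
   from distance and consistency summaries, mirroring how such electrodes are
   excluded in clinical practice.
4. A ray from the RN cross-section centroid through the electrode point is
   intersected with the STN mesh (Möller–Trumbore over all faces). The
   **ventral border** is operationalized as the exit intersection (outward
   normal · direction > 0) with the largest +Z (most inferior) coordinate,
   ties resolved to the largest ray parameter: the ray travels laterally from
   the RN toward the electrode, so the far-side, most-inferior crossing is the
   ventral border. The border is defined this way because no standard
   geometric definition exists; the ventral border is simply the boundary
   segment most reliably identified on T2 imaging. When the ray misses the
   STN entirely (electrode well posterior/lateral of the nucleus at that
   level) the electrode keeps its positional category but no distance — a
   condition of class `dbsreco_no_intersection` that callers can trap.
5. The positional category is `within` if the electrode point falls inside
   the STN cross-section polygon (even–odd rule); otherwise the dominant
   axis-wise offset from the section centroid decides: medial/lateral by X
   (hemisphere-aware, lateral = away from the midline), anterior/posterior by
   Y, with exact ties broken to the lateral/medial axis (documented,
   deterministic).

An open choice: "the electrode" in the ray construction could be the
trajectory's plane intersection or the nearest contact center. The package
uses the plane intersection (`electrode_point_at_level()`), which is
continuous in the geometry; the nearest-contact alternative would quantize to
2 mm steps.

Point-in-mesh classification (`contact_subregion()`) uses the generalized
winding number (van Oosterom–Strackee solid angles, threshold 0.5), with
points within `surface_tol` of the surface counting as **inside**: a contact
touching the border counts as overlapping, matching how overlap is assessed
visually.

## Statistical ladder

* **Normality.** `ks_normality()` is a Lilliefors-corrected one-sample KS test
  (via `nortest::lillie.test`); the plain KS test with parameters estimated
  from the sample is anti-conservative. The correction's p-approximation
  requires n ≥ 5; smaller samples raise an insufficient-sample error, and the
  two-method gate falls back to the paired t for such tiny samples.
  Constant samples (zero SD) are rejected as undefined.
* **Two methods.** Paired t when the paired differences pass the gate at
  α = 0.05, Wilcoxon signed-rank otherwise, gated per comparison (per
  axis and scope). Degenerate all-equal differences report p = 1 (identical
  methods) or p = 0 (exact constant shift) rather than NaN.
* **Three paired conditions.** When every pairwise difference set passes the
  gate: repeated-measures ANOVA (`aov(value ~ method + subject)`) with
  Tukey's HSD on the within-subject MSE and its (n−1)(k−1) df. Otherwise:
  Friedman test, then Dunn's multiple comparison — z on within-block rank
  means with SE `sqrt(k(k+1)/(6n))`, two-sided, Bonferroni over the three
  pairs, without tie correction (classic form). Constant difference sets
  route to the rank path (the parametric MSE could collapse to zero);
  all-identical conditions short-circuit to p = 1. Incomplete triplets are
  dropped listwise with a logged count.
* **Pairing unit.** Bilateral electrodes are paired as electrodes (n = 52),
  not patients (n = 26): the discrepancy of interest is per-reconstruction,
  and hemispheres contribute independent localizations. Within-patient
  correlation of the two hemispheres would, if present, make the paired test
  slightly conservative rather than anti-conservative.
* **Rounding.** Reported discrepancies are rounded to 2 decimals and
  percentages to 1 decimal; all internal computation is full precision.

The parametric post hoc p-values are approximations. The test suite compares
them against an exact enumeration of all 3!^n within-block permutations on
n = 6 fixtures: the Tukey route tracks the exact max-statistic null within
0.02; Dunn's normal approximation of the discrete rank statistic is within
0.03 in the decision-relevant range (p ≤ 0.2) and agrees on every
significance call, but deviates by up to ~0.2 for clearly non-significant
pairs — inherent to any normal approximation of a 6-block rank statistic, not
a defect of the implementation.

## The synthetic cohort: what it emulates, and what it does not

`simulation_config()` defaults describe the study conditions the pipeline is
designed around: 26 bilaterally implanted patients (52 electrodes), a
planning-system-like method B biased by (−0.13, −1.16, +0.59) mm against a
toolbox-like method A, both with 1 mm per-axis landmark noise. Anatomy is
analytic: an STN ellipsoid with semi-axes (5, 3, 2) mm obliquely oriented
toward the posterior-lateral-dorsal pole, centered (±10.5, 12.5, 3.5) mm, and
a 3 mm RN sphere at (±5.5, 7, 3.5) mm, medial-posterior to the STN — one
template anatomy mirrored exactly across the midsagittal plane, playing the
role of an atlas. The dorsolateral (sensorimotor) subregion is the STN beyond
the 60th percentile of vertex projections on the structure's first principal
axis, toward that pole: a qualitative stand-in for the sensorimotor partition
of probabilistic atlases, not a reproduction of any atlas geometry.

Choices worth knowing:

* **Bias and target offset are hemisphere-symmetric** (lateral, anterior,
  inferior): the X component is mirrored for the left side before application
  in the physical frame. Without the mirror, magnitude pooling would cancel
  lateral bias between hemispheres.
* **Noise enters at the landmark points** (ventral contact, cranial point at
  40 mm), not at finished contacts, so interpolation error propagation is
  exercised exactly as in the real workflows.
* **The planned target** defaults to the dorsolateral centroid shifted
  5.25 mm deeper along the canonical approach (17% lateral, 34% anterior,
  92% superior-to-inferior descent), so that the four implanted contacts
  straddle the dorsolateral region and the contact span reaches the maximum
  RN level — as implanted electrodes do. Tip placement deviation from plan is
  isotropic Gaussian with SD 0.5 mm (no published distribution exists; this
  is an assumption, configurable), entry directions are drawn uniformly in a
  5° cone, and MER depth readings carry 0.3 mm Gaussian noise, clipped at
  zero.
* **Determinism.** One base seed feeds per-patient, per-stage substreams
  (31-bit multiplicative mixing), so replicate cohorts, reruns, and cohort
  growth are all reproducible; re-running a pipeline from its manifest
  reproduces the CSV outputs byte for byte.

What the generator does **not** emulate: anatomical variability across
patients (one template anatomy; coordinate spread comes from placement
deviation and noise), brain shift and pneumocephalus, electrode bending, CT
metal artifacts, image co-registration error structure (noise is iid
Gaussian), and clinical outcome scores. Consequently, a passing suite shows
that the *computational chain* is correct and well calibrated under its
stated noise model — not that any particular clinical agreement number
generalizes. Two visible consequences: the categorical consistency between
the two synthetic methods (~40–50% at 1 mm noise) is lower than manual
clinical consistency assessments, which judge coarser features; and the
tip-to-target Euclidean distances of both methods exceed the MER-recorded
distance systematically, because with sub-millimeter true tip–target
distances the chi-type inflation `E‖d + ε‖ > ‖d‖` of 1 mm localization noise
dominates — in clinical cohorts, where true distances are larger, the same
comparison is typically non-significant. The distance-validation property
(no significant pair when noise is small relative to true distances) is
therefore exercised in the tests at reduced noise.

## Numerical choices and problem sizes

Meshes are icosphere subdivisions (level 3, 1280 faces, for shipped anatomy;
volumes match analytic values within 1%). Mesh validity demands closedness
(every undirected edge in exactly two faces, once per direction),
outward orientation, and triangle areas above 1e−12 mm². Convex plane
clipping (used to carve the dorsolateral subregion) retriangulates cut faces,
caps the cut ring by an angular-ordered fan, snaps the cut plane to a
midpoint between distinct vertex projections (tessellation symmetry otherwise
places vertices exactly on the plane), and welds vertices within 1e−9 mm.

The test suite sizes its simulations to keep full runs around a minute:
100 replicate cohorts for parameter recovery (recovered per-axis discrepancies
within 3σ/√52 ≈ 0.42 mm of the injected bias, with the small-X/large-Y
rejection pattern), 1000 replicate cohorts for type-I calibration of the
paired t (empirical rejection 5% ± 2% at α = 0.05), 1000 random ray
configurations against the line–sphere closed form (agreement bounded by the
tessellation sagitta; the ray–mesh algorithm itself matches a brute-force
per-triangle oracle to 1e−6), and full 3!^6 permutation enumerations for the
post hoc oracles.

## Known limitations

* Cross-section chaining assumes the section polygons are disjoint loops
  (true for the package's convex-component anatomy); nested loops (holes)
  would be area-summed, not subtracted.
* `clip_mesh_plane()` is correct for convex meshes only.
* The ventral-border operationalization and the positional category
  vocabulary are deterministic stand-ins for what is, clinically, a manual
  judgment; consistency percentages are comparable across runs of this
  package but not directly against visually assessed rates.
* Dunn's z uses no tie correction; with heavy ties (e.g. duplicated
  conditions) its p-values are conservative.
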