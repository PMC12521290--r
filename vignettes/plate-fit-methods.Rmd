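---
title: "Quantifying the anatomical fit of a pre-contoured distal femur plate"
author: "platefit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the anatomical fit of a pre-contoured distal femur plate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Pre-contoured lateral distal-femur locking plates are factory-shaped to the
average anatomy of their target population. How well a given plate actually
conforms to a given femur is clinically consequential: when the gap between
plate undersurface and bone is large and the plate is used as a reduction
template, the distal fragment can be pulled into valgus malalignment. The
protocol implemented here makes plate fit a measurable quantity on 3D
surface models: a plate undersurface is positioned on the lateral distal
femur under explicit surgical constraints, plate-to-bone distances are
measured at a fixed layout of points, three distance criteria decide
anatomical fit, and the femoral anterior-bow radius of curvature (ROC)
supplies the morphological covariate that drives shaft misfit.

`platefit` implements that protocol end to end as reusable, tested code:
mesh input/output and geometric queries, constrained rigid positioning,
distance measurement and criterion evaluation, ROC measurement, and
nonparametric cohort statistics. Because the bone surface models behind the
original cohort study are not publicly deposited, the package also ships a
first-class synthetic anatomy module: parametric femora and plates on which
every stage of the pipeline is exercised and validated. All results the
package produces on synthetic cohorts are qualitative analogues of the
clinical findings (directions and orderings), not reproductions of the
clinical magnitudes.

## The distance metric

All plate-bone distances are *vertex distances*: the Euclidean distance
from a point of interest on the plate to the nearest vertex of the bone
mesh, with ties broken toward the lowest vertex index. This deliberately
mirrors the original measurement semantics (a batch script that scanned
every bone vertex) rather than the more common point-to-triangle distance.
The consequence is a granularity floor set by the mesh vertex spacing, which
is why the synthetic generators enforce a target edge length of at most
1 mm — far below the 1/2/3 mm criterion thresholds — and why the contact
zones used during positioning are sampled at four times the lattice density.
`nearest_vertex_distance()` provides both an exhaustive scan and a
grid-accelerated search that returns the identical minimum (this equality is
asserted in the test suite on randomised instances).

## Synthetic anatomy

`femur_params()` / `make_femur()` build an idealised femur in a canonical
left-side frame (z along the shaft, x anterior, y lateral):

* The intramedullary canal centreline is straight below the distal
  diaphysis level and follows a circular arc of configurable radius
  `r_bow` (tangent-continuous) above it. Keeping the condylar block
  identical across bow radii is what makes one plate family applicable to a
  whole synthetic cohort; the price is that the arc's apex sits at the
  distal diaphysis level rather than mid-shaft, which is immaterial for the
  ROC (the fitted circle radius is the arc radius either way).
* Cross-sections are ellipses (condyle semi-axes 26 x 34 mm tapering to a
  13 mm circular shaft), with an intercondylar notch carved posteriorly
  over the distal 20 mm and a flat lateral condylar facet inclined 10
  degrees medially — the feature that makes the plate head appear rotated
  in a lateral view.
* Outer and inner cortex meshes are closed lattice tubes (watertight by
  construction, verified by an edge audit); landmarks — lesser trochanter
  base, lateral condyle start, the two distal contact points, the
  intercondylar fossa region, and a lateral shaft ridge polyline — are
  computed analytically from the construction.

The femur is schematic by design: the protocol's mathematics needs a
controllable bow, landmarks, and a condylar contact geometry, not
statistical shape realism. Passing tests on these models therefore
demonstrate the correctness of the *protocol machinery*, not the clinical
accuracy of any specific fit percentage. Features of real femora that the
generator does not emulate include lateral (coronal) bow, cortical
thickness variation, anteversion, and subject-specific condyle shape.

`plate_params()` / `make_plate()` build 9/11/13-hole plate undersurfaces as
structured point grids over a lateral band of a template femur: the head
(over condyle and metaphysis, 60-120 degrees of the section) conforms to
the template, while the shaft narrows to an 11 mm strip and follows its own
sagittal arc, 940 mm by default — the reverse-engineered shaft ROC of the
clinical plate. Plate dimensions are configuration, not data: the hole
pitch (20 mm) is chosen so the criterion-3 rows at 40 mm spacing number
5/6/7 for the three lengths, reproducing the published measurement-point
counts (16/19/22), and each longer plate adds exactly two hole pitches of
shaft. Screw trajectories are populated with head screws running medially
across the condyle and the most proximal screw aimed at the template canal
centreline.

`sample_cohort()` draws a two-ethnicity cohort (default 159 subjects in
eight strata by ethnicity, age group at the 65-year cut, and sex) with
stratum heights as truncated normals and the bow radius linked to height by
a per-ethnicity linear calibration with Gaussian noise, clipped to
400-1800 mm. The calibration (common slope 10 mm/cm, intercepts set so the
ethnic stratum medians land near 976 mm and 846 mm, residual SD 185 mm) was
fitted once so that the cohort reproduces the published stratum medians to
within sampling error and a height-ROC rank correlation near 0.45; it is
configuration, not a code constant. Diaphysis length scales with stature
(2.62 mm per cm of height minus the fixed 90 mm taken by condyle, distal
offset and proximal segment), which reproduces the expected plate-length
distribution (11-hole plates for shorter subjects, 13-hole for taller).

## Plate positioning

The original protocol positioned plates interactively. `refine_position()`
automates it deterministically:

1. `initial_alignment()` computes a closed-form (Kabsch) rigid fit of four
   landmark correspondences: the two distal contact anchors, the
   centre-curve point at the lateral-condyle-start level, and the shaft
   zone anchor against the lateral shaft ridge at matching arc length.
   The four points span a tetrahedron, so all six degrees of freedom are
   pinned without any surface search.
2. A *seating phase* minimises the squared distances of the three zone
   anchors to their landmark targets under a softened collision penalty.
   This phase supplies the tangential gradient that a pure contact
   objective lacks (sliding a conforming plate along the bone barely
   changes contact distances).
3. A *contact phase* minimises the protocol objective: the sum of squared
   contact-zone distances (distal anterior, distal posterior, and the
   shaft zone at 60% of the shaft span; each zone distance is the minimum
   vertex distance over a 5 mm patch of densely sampled undersurface)
   plus `lambda` (default 1000) times the sum of squared penetration
   depths over all undersurface samples. Containment is decided by ray
   parity against the watertight outer cortex; penetration depth is the
   projection of the offset to the nearest vertex onto that vertex's
   outward normal, which stays near zero for grazing contact instead of
   inheriting the tangential lattice offset.

Both phases use a pattern search over the six rigid degrees of freedom
(translations along and rotations about bone-anchored axes, rotations
pivoting at the distal contact midpoint), with Hooke-Jeeves pattern moves,
step halving from 1 mm / 0.01 rad down to 1e-4, and up to three
seat-then-polish rounds. Every ingredient is derived from the bone and
plate alone, so the result is equivariant under joint rigid motion of the
pair, and there is no randomness anywhere in the optimiser.

A result is *converged* when all three contact zones are within 0.2 mm, no
undersurface sample penetrates the bone, no screw passes within 2 mm of the
intercondylar fossa region, and the most proximal screw tip lies inside the
inner cortex — all re-verified on the full bone model after the search,
independent of any optimiser state. When simultaneous contact is
geometrically impossible (a rigid plate cannot touch three zones on a bone
whose bow differs too much from its own), the result reports
`converged = FALSE` and the cohort pipeline excludes the bone with a
logged reason; no ranking of partial solutions is attempted. With the
default geometry this feasibility window spans roughly 820-1150 mm of bone
bow against the 940 mm plate — itself a quantitative expression of the
clinical observation that one pre-contoured shape cannot serve strongly
bowed femora.

## Fit criteria and measurement layout

`build_layout()` places the measurement points in the plate construction
frame: one most-anterior distal point (criterion 1, threshold 1 mm), a
3 x 3 metaphyseal grid whose first-row centre is the distal plate tip
(criterion 2, 2 mm), and anterior/centre/posterior shaft rows spaced
exactly 40 mm apart from the head-shaft transition plus the proximal tip
point (criterion 3, 3 mm). Shaft length residues shorter than one row
pitch are absorbed before the tip point. All thresholds are inclusive, a
criterion passes only if *every* one of its points is within threshold,
and overall anatomical fit is the conjunction of the three. The criterion-1
point and the nine criterion-2 points are disjoint sets (the texts treat
them as separate criteria). Distances are always measured to the outer
cortex only.

`select_plate_length()` implements the longest-plate rule: the largest
available hole count whose proximal tip stays at least 20 mm (inclusive)
distal to the lesser trochanter base when the plate sits distally flush.

## Bow radius measurement

`measure_bone_roc()` cuts the inner cortex with 20 planes perpendicular to
the diaphyseal principal axis, equally spaced (endpoints included) between
the lesser-trochanter level and 10 mm proximal to the lateral condyle
start. The "centre point" of each section is the area centroid of its
outermost closed loop — robust to non-uniform loop sampling, and within
measurement noise of the boundary-point mean for near-elliptical canals.
`fit_circle_3d()` fits a least-squares plane (SVD), projects the centroids
into it, initialises a circle algebraically (linear least squares) and
refines it with a Gauss-Newton geometric step; it is exact to numerical
precision on noiseless circles, rigid-invariant, scale-equivariant, and
errors out on collinear input rather than reporting a pseudo-infinite
radius. `measure_plate_roc()` applies the same fit to the shaft portion of
the plate centre curve. On synthetic bones the generating bow is recovered
within 2% across 600-1700 mm (the residual is pure discretisation), and the
default plate measures 940 mm to numerical precision.

## Cohort statistics

`mann_whitney_u()`, `chi_square_fit_rates()` and `spearman_rho()` wrap the
base R implementations with the protocol's conventions fixed: exact
Mann-Whitney p-values for `min(n) <= 8` without ties and the normal
approximation with tie correction (no continuity correction) otherwise;
Pearson chi-square without Yates correction; Spearman p by the t
approximation. All are two-sided at alpha = 0.05 and no multiple-testing
correction is applied, matching the reporting conventions of the protocol.
`make_tables()` produces the four table analogues: stratum descriptives
reported as median with SD and range (the protocol's convention — the
unusual median-with-SD pairing is reproduced as printed, not "corrected"),
pairwise descriptive tests, per-criterion fit summaries with satisfied
counts and percentages, and pairwise fit tests. Degenerate strata yield
rows with `n = 0` and blank statistics; single-subject strata report blank
SDs.

## Numerical choices

* Containment classifies points within 1e-9 mm of the surface as outside
  (non-penetrating); the test is on the perpendicular distance to the
  triangle plane, so grazing rays are handled correctly, and ambiguous
  (edge-grazing) rays retry with deterministic jittered directions.
* Plane sections that would pass exactly through vertices are nudged by
  1e-7 mm along the normal before cutting.
* Equidistant nearest vertices resolve to the lowest index in both the
  exhaustive and accelerated paths.
* The "about 4 cm" row spacing is fixed at exactly 40 mm and the "about
  10 mm" distal diaphysis offset at exactly 10 mm; both are
  config-overridable.
* Units are millimetres throughout; mesh files carry no unit metadata, so
  the readers expose a multiplicative scale factor.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
geometry generated at call time: femora at 1 mm resolution (about 85k
outer-cortex vertices), cohorts of 3-10 bones for positioning studies and
159 metadata-only subjects for calibration checks, 200-replicate
Monte-Carlo loops for the circle fit, and single-bone sweeps over four bow
radii for recovery checks. These sizes keep any single check within a few
minutes on one core while leaving the granularity of every distance far
below the decision thresholds.

## Known limitations

* The synthetic femur has no lateral bow and a simplified trochanteric
  region; effects that depend on coronal-plane shape are out of reach.
* Vertex-distance semantics tie measured distances to mesh resolution;
  results on meshes coarser than ~1 mm are not comparable.
* The positioning automation reports infeasibility where an experienced
  surgeon might accept a compromise seat; cohort fit percentages on
  synthetic data are therefore conditional on convergence.
* Clinical magnitudes (e.g. mean proximal-tip gaps of 11-16 mm) are not
  reproducible on the idealised geometry; the package reproduces the
  *mechanisms* — tip misfit growing with bow mismatch and shrinking with
  stature under a positive height-bow coupling — as sign and ordering
  properties.
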