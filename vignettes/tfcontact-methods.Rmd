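---
title: "Measuring tibiofemoral contact and its reliability: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring tibiofemoral contact and its reliability: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfcontact)
```

This vignette documents the measurement model, the statistical model, the
synthetic phantom that stands in for scan data, and the numerical and
design decisions behind each — in that order.

## The measurement model

The substrate is a voxelized segmentation (`label_volume`): a 3-D integer
grid with anisotropic spacing, in which tibial plateau, tibial cartilage,
femoral cartilage and per-compartment contact regions each carry one
label. World coordinates use the voxel-centre convention (`origin` is the
centre of the first voxel), matching standard NIfTI semantics and making
centroids unambiguous.

**Contact area** follows the tracing-based formula: the number of contact
voxels multiplied by the in-plane voxel dimensions, `A = n·dx·dy`. Two
points deserve emphasis.

* The formula is independent of slice thickness. Contact is traced as an
  axial footprint; a 2.5 mm slab contributes the same in-plane area as a
  0.1 mm one.
* Only tibial-surface voxels are counted (one voxel per in-plane column of
  the contact interface). Pooling femoral- and tibial-side contact voxels
  would double-count every column; the tibial surface is also where
  centroids are reported. Since tracing conventions vary on this point, a
  `projected = TRUE` variant is provided that counts each in-plane column
  at most once regardless of how many voxels it holds; the default is the
  literal voxel count.

**Normalization** divides by the maximum axial cross-sectional area of the
tibial plateau, computed as the largest per-slice voxel count times
`dx·dy`. The plateau mask here is the bone-surface label; whether cartilage
should be included in the denominator is a genuine ambiguity of such
protocols — the phantom sidesteps it by construction (its plateau and
cartilage footprints coincide), and real users can pass either mask.

**Contact detection** (`extract_contact`) emulates "no visible
separation": for every in-plane column, the topmost tibial-cartilage voxel
is contact when the nearest femoral voxel above it is within
`gap_tolerance_mm`. The separation is counted in empty voxels between the
surfaces times the slice thickness, so touching labels give separation 0,
and interdigitated columns (femoral at or below the tibial top) are
contact at any tolerance. The default tolerance of one through-plane
spacing encodes that a sub-slice gap cannot be resolved at the
acquisition's resolution: surfaces in adjacent slices count as touching,
one full empty slice does not.

**Centroids** are arithmetic means of contact-voxel world coordinates. An
empty mask yields an explicitly flagged undefined centroid (`NA` +
`centroid_defined = FALSE`), never a silent zero — a silent (0,0,0) would
silently corrupt downstream ratings tables.

## The anatomical frame

Centroid locations are only comparable across subjects in an anatomical
frame. `build_tibial_frame()` constructs a right-handed orthonormal basis
from four landmarks: ML axis from the medial to the lateral plateau edge;
SI axis from a distal shaft point toward the plateau centre,
Gram–Schmidt-orthogonalized against ML; AP = SI × ML. ML is fixed first
and SI adjusted because plateau edge points are the most reliably
identified landmarks of this convention. Construction is
translation-invariant and rotation-equivariant (tested over random rigid
motions), and degenerate landmark sets (coincident edges, shaft collinear
with the edge axis) are rejected rather than silently regularized.

Percent coordinates divide the frame coordinate by the plateau's extent
along that axis: 0 % at the medial/posterior extent boundary, 100 % at the
lateral/anterior one. The extents come from the plateau mask's bounding
interval along the frame axes (not from the contact patch), so percent and
millimetre coordinates are mutually convertible through the extents as an
exact identity — which the reports exploit (below). Points off the plateau
are returned as computed but flagged.

A supine-to-upright registration, when one exists, enters as a validated
`rigid_transform` (proper orthonormal to 1e-9) applied to landmarks;
image-to-image registration itself is out of scope.

## The reliability model

Ratings tables are balanced `n × k` matrices (subjects × repeated
measurements) labelled with their design: two raters on one scan
(inter-rater), one rater on two sessions (test-retest), or one rater, three
repeats (intra-rater, analysed as one `k = 3` table).

`icc31()` fits the two-way mixed-effects, single-measure, consistency
ICC for fixed raters. From the two-way decomposition (`BMS`, `JMS`, `EMS`
on `n−1`, `k−1`, `(n−1)(k−1)` df),

\[ \mathrm{ICC}_{3,1} = \frac{BMS - EMS}{BMS + (k-1)\,EMS}. \]

Fixed raters means column shifts cancel: adding any constant to one
measurement column leaves the estimate unchanged (a tested invariant).
Confidence intervals are the exact F-based ones: with `F = BMS/EMS`,
`F_L = F / q_{1-α/2}(n−1, (n−1)(k−1))` and
`F_U = F · q_{1-α/2}((n−1)(k−1), n−1)`, each mapped through
`(F*−1)/(F*+k−1)`. The p-value is the F test of the subject effect — the
natural companion of this estimator, used because reliability tables
conventionally print one. Choices for edge cases:

* `EMS = 0` with subject variance: ICC = 1 with degenerate CI [1, 1] and a
  warning flag (arises in zero-noise simulations).
* `BMS = EMS = 0` (constant table): an error; no reliability is defined.
* Negative estimates are reported as computed, not truncated at zero —
  truncation would bias small-sample summaries and published tables do
  print negative CI bounds.

**SEM and SDC.** No single SEM formula is universal; this package uses the
classical consistency companion `SEM = SD·√(1−ICC)` with SD taken over the
table cells after removing measurement-column means (the spread the
consistency ICC actually partitions). `SDC₉₅ = 1.96·√2·SEM`. In reports,
the absolute-unit SEM is derived from the percent SEM through the
cohort-mean plateau scale (plateau cross-section for areas, plateau extent
along the axis for centroids). Consequence: `SDC/SEM = 2.7719…` exactly
and percent↔absolute columns are exact conversions in every row — internal
identities the test suite asserts rather than empirical claims.

**Interpretation bands**: poor < 0.5 ≤ moderate < 0.75 ≤ good ≤ 0.9 <
excellent. The upper class wins at 0.5 and 0.75, but 0.9 itself is *good*:
only strictly greater than 0.9 is excellent. **Accuracy** is the mean
absolute error of paired test/reference measurements.

## The phantom: what it emulates, and what it does not

The phantom replaces scans and raters with an analytically known object: a
flat elliptical plateau (default semi-axes 35 × 30 mm, maximum cross
section π·35·30 ≈ 3299 mm²) carrying 2.5 mm cartilage layers and two
elliptical contact patches — medial 12 mm (π·12² ≈ 452 mm²), lateral 10 mm
(π·10² ≈ 314 mm²), i.e. normalized areas near 13.7 % and 9.5 %, the scale
of standing-knee measurements in vivo. Outside the patches the femoral
surface sits 7.5 mm (three slices) above the tibial surface, comfortably
beyond the default gap tolerance. The default grid is 104 × 104 × 16
voxels at 0.859 × 0.859 × 2.5 mm, an upright-MRI DESS geometry. Every
structure is an extruded ellipse, so area, centroid and plateau
cross-section have closed forms and voxelization error is bounded by
perimeter × in-plane voxel diagonal (first order in voxel size) — the
bound the fidelity tests use at 0.859 mm and 0.1 mm spacing.

**Rater noise** toggles voxels on the in-plane 4-connected contour of each
contact patch (raters trace contours on axial slices, so contour noise is
in-plane by nature; the patch is one voxel thick along z, where a 3-D
boundary would degenerate to the whole mask). `boundary_flip_prob` sets
the magnitude; `erosion_dilation_bias` ∈ [−1, 1] tilts toward under- or
over-segmentation. Because the dilatable outer contour has a few more
voxels than the erodible inner one, naive symmetric probabilities would
inflate area; add/remove probabilities are therefore balanced against the
contour sizes so zero bias gives exactly zero expected signed area change
(tested over 120 seeds). At full positive bias and unit probability the
operation reduces to a morphological 4-dilation constrained to cartilage,
which the tests check against a brute-force oracle.

**Session noise** acts in specification space, before voxelization:
lognormal jitter on patch semi-axes (cartilage load response) and an
in-plane rigid pose change of the whole phantom. Restricting pose to the
axial plane keeps the geometry flat in the grid, so the jittered phantom's
ground truth remains exact; out-of-plane tilt would require resampling and
forfeit the analytic truth. Jitter draws are truncated at ±2 SD so every
sampled geometry is valid — a realistic posture change is small, and an
unbounded tail would occasionally put a patch outside the plateau.

**Cohort variation** (in `run_study`): a shared knee-size factor (sdlog
0.08) scaling plateau and patches together, per-compartment patch factors
(sdlog 0.08), and patch-centre jitter (SD 3 % of the plateau semi-axes).
Together these give absolute areas a CV near 23 % and normalized areas
near 16 %, matching the between-subject spread reported for standing
knees, and — critically — give centroids genuine between-subject variance,
without which centroid reliability coefficients would be estimating noise
against nothing. Rater noise defaults (flip probability 0.25, biases
∓0.15) were chosen to produce area SEMs of a few tenths of a percent of
the plateau cross-section, the order of magnitude printed in reliability
studies of this measurement; no attempt is made to reproduce any
particular published ICC, which depends on the specific cohort and raters.

What the phantom does **not** model: MR signal formation (no DESS model,
noise fields or denoising), menisci/ligaments/bone shape, curved contact
surfaces, out-of-plane posture change, and spatially correlated rater
error along the contour. Passing tests therefore demonstrate correctness
of the measurement and statistics pipeline on geometrically clean inputs,
not segmentation performance on real images.

## Numerical choices and problem sizes

* Patch containment and grid-fit checks sample 256 ellipse boundary
  points; strict inequality is required.
* Compartment split tie-break: ML coordinate ≤ 0 is medial, > 0 lateral
  (voxel centres rarely land exactly on the frame plane; when they do the
  medial side wins, deterministically).
* Orthonormality tolerances are 1e-9 for frames and rigid transforms; the
  ANOVA guards residual sums of squares against tiny negative
  floating-point cancellation (relative 1e-8).
* Random streams: every stage derives its own sub-seeds from the master
  seed (`sample.int` after `set.seed`), so stages are reproducible
  independently and whole studies are byte-identical across runs.
* Default study sizes — 5 subjects, 104 × 104 × 16 grids, 500-replicate
  coverage runs, 1000-table oracle comparisons at n ≤ 8 — keep the full
  suite and the acceptance script in the tens of seconds while leaving
  Monte-Carlo error well inside the asserted bands.

## Known limitations

* The consistency ICC deliberately ignores systematic rater offsets; an
  absolute-agreement form (ICC(2,1)) is not implemented.
* SEM uses the column-centred pooled SD; with strong subject-by-rater
  interaction other SD choices give slightly different absolute SEMs (the
  percent/absolute identities are unaffected).
* `extract_contact` scans columns along the grid's z axis; a strongly
  tilted joint would need resampling into an axial frame first.
* Areas follow the voxel-count formula and so inherit its slight
  overestimation of steeply curved contact (not present in the flat
  phantom).
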