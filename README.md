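# tfcontact

Voxel-based measurement of tibiofemoral cartilage contact, and the
reliability statistics needed to interpret such measurements.

When the knee is imaged standing, the regions where tibial and femoral
cartilage meet with no visible separation can be traced slice by slice on
the segmented volume. From those label volumes this package computes, per
compartment (medial / lateral):

- **contact area** — number of contact voxels × in-plane voxel dimensions,
  `A = n · dx · dy` (mm²), independent of slice thickness;
- **normalized contact area** — `100 · A / A_plateau` (%), where
  `A_plateau` is the maximum axial cross-sectional area of the tibial
  plateau, removing between-subject size differences;
- **contact centroid** — the geometric centre of the contact voxels,
  expressed in a landmark-built tibial anatomical frame (Grood–Suntay
  style: medial→lateral, posterior→anterior, inferior→superior axes) both
  in mm and as percent position on the plateau (medial 0 % → lateral
  100 %, posterior 0 % → anterior 100 %).

Because segmentation-derived metrics are only as useful as they are
repeatable, the package implements the companion reliability toolkit:

- **ICC(3,1)** — two-way mixed-effects, single-measure, consistency
  intraclass correlation for fixed raters,
  `ICC = (BMS − EMS) / (BMS + (k−1)·EMS)`, with exact F-based
  (Shrout–Fleiss) confidence intervals and the F test of the subject
  effect;
- **SEM** — standard error of measurement, `SEM = SD·√(1 − ICC)`;
- **SDC₉₅** — smallest detectable change, `SDC₉₅ = 1.96·√2·SEM`;
- qualitative bands (poor < 0.5 ≤ moderate < 0.75 ≤ good ≤ 0.9 <
  excellent) and **MAE** accuracy against a reference modality.

Since no scan data ship with the package, a synthetic phantom module
generates knee-contact label volumes with analytic ground truth (elliptical
plateau, elliptical contact patches, so areas and centroids have closed
forms), plus rater-noise and session-noise models — enough to exercise and
validate every stage of the pipeline, including whole simulated
reliability studies (`run_study()`).

Intended users: musculoskeletal imaging researchers quantifying joint
contact from MRI segmentations, and anyone needing a tested ICC/SEM/SDC
implementation with a simulation harness.

## Worked example

```r
library(tfcontact)

# a phantom at upright-MRI resolution (0.859 x 0.859 x 2.5 mm voxels)
ph <- generate_phantom(phantom_spec())
measure_contact(ph$volume, ph$landmarks)
#> Tibiofemoral contact measurement
#>  compartment area_mm2 area_pct centroid_ml_mm centroid_ap_mm centroid_ml_pct
#>       medial   454.53    13.73         -17.48              0           24.88
#>      lateral   312.86     9.45          19.27              0           77.70
#>  centroid_ap_pct centroid_defined plateau_area_mm2 ...
#>               50             TRUE          3311.61 ...
```

The medial patch was constructed with analytic area π·12² = 452.4 mm²; the
voxel count at 0.859 mm spacing measures it as 454.5 mm² (the discrepancy
is bounded by patch perimeter × voxel diagonal and shrinks linearly with
voxel size). Normalized area 13.7 % is the medial contact fraction of the
3299 mm² plateau cross-section; the centroid sits a quarter of the way
across the plateau from its medial edge (24.9 % ML).

```r
rt <- simulate_ratings(30, 2, subject_sd = 3, error_sd = 1, seed = 42)
icc31(rt)
#> ICC(3,1) = 0.923 (95% CI 0.844 to 0.962), p = <0.001 -- excellent reliability
#>   30 subjects x 2 measurements (inter_rater)

sdc95(18.9)   # SEM of 18.9 mm2 -> smallest detectable change 52.4 mm2
#> [1] 52.38813
```

`run_study(study_config(seed = 1))` runs a full synthetic study (5
subjects; inter-rater, test-retest and intra-rater designs; an accuracy
sub-study against a fine-resolution re-measurement) and prints one
reliability report per design, each row carrying ICC with CI, SEM and
SDC₉₅ in % and absolute units. A thin CLI with the same stages lives in
`inst/scripts/tfcontact` (subcommands `generate`, `measure`,
`reliability`, `accuracy`, `run-study`).

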