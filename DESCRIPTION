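Package: tfcontact
Title: Tibiofemoral Cartilage Contact Area, Centroid Location and
    Measurement Reliability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies tibiofemoral cartilage contact from voxelized
    segmentation label volumes: per-compartment contact area, contact area
    normalized to the maximum axial cross-section of the tibial plateau, and
    contact-centroid location expressed in a landmark-defined tibial
    anatomical frame (millimetres and percent of plateau extent). Provides a
    measurement-reliability toolkit -- two-way consistency intraclass
    correlation ICC(3,1) with exact F-based confidence intervals, standard
    error of measurement (SEM), smallest detectable change (SDC95),
    qualitative interpretation bands and mean absolute error -- together
    with a synthetic knee-contact phantom generator with analytic ground
    truth and rater/session noise models, so that the entire pipeline from
    label volume to reliability report can be exercised and validated
    without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
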