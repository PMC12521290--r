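Package: platefit
Title: Anatomical Fit Assessment of Pre-Contoured Distal Femur Plates on 3D Bone Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantitative protocol for assessing the anatomical fit of a
    pre-contoured lateral distal-femur locking plate on triangle surface
    models of the femur. Provides mesh input/output (STL, PLY) and geometric
    queries, parametric synthetic femora and plate undersurfaces for
    protocol validation, constrained rigid plate positioning with contact,
    collision and screw-trajectory checks, plate-bone distance measurement
    against three clinical fit criteria, femoral and plate anterior-bow
    radius-of-curvature measurement by best-fit circle, and nonparametric
    cohort-level statistics with table-style summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
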