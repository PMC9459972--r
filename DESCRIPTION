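Package: facesym
Title: Quantifying Facial Palsy from 3D Facial Landmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Registers 478-point (or 68-point) 3D facial landmark sets captured
    at different times or expressions using a scale-sweep registration pipeline
    (per-landmark scale matching, feature-based global registration, and
    point-to-plane ICP refinement with minimum-inlier-RMSE selection), and
    quantifies facial-palsy progression with three midsagittal-plane symmetry
    statistics: distance symmetry, angle symmetry, and left-right landmark
    movement asymmetry, aggregated over 17 facial-muscle groups. Includes a
    procedural synthetic-face generator with smile deformation, one-sided palsy
    attenuation, and similarity-transform disturbance for validation, plus a
    command-line interface for registration, symmetry reports, and longitudinal
    tracking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
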