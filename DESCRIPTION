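Package: mousegaze
Title: Gaze and Visual-Field Reconstruction for Freely Moving Mice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the visual experience of freely moving mice during prey
    pursuit from tracked head, eye and prey coordinates. Provides head-frame and
    eye-rotation geometry (rotation composition, geodesic interpolation, rigid
    fiducial registration, horizon alignment), ocular-torsion estimation from a
    tracked corneal spot with anatomical calibration, a schematic mouse eye with a
    gradient-index (GRIN) lens including ray tracing, lens optimization,
    retina-to-cornea projection and parameter-sensitivity analysis, per-frame
    corneal-view rendering of a triangle-mesh environment, spherical optic-flow
    fields and flow-pole densities, binocular alignment and overlap statistics with
    eye-freezing counterfactuals and vestibulo-ocular compensation gains,
    pursuit-epoch classification with trajectory-straightness and prey-image
    density metrics, and seeded synthetic-data generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    Matrix,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
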