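Package: hipmorph
Title: Automated Landmark-Based Radiographic Hip Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Computes eight radiographic hip-morphology measurements
    (acetabular depth-width ratio, modified acetabular index, alpha angle,
    Wiberg and lateral center-edge angles, extrusion index, neck-shaft
    angle, triangular index ratio) from 2-D bony-outline landmark point
    sets such as those produced by automated shape-model annotation of AP
    pelvic radiographs.  Classifies radiographic morphological diagnoses
    (acetabular dysplasia, pincer and cam morphology, coxa vara and valga)
    with literature thresholds, and provides the reliability and agreement
    statistics used to validate such pipelines: two-way intraclass
    correlation coefficients with exact F confidence intervals,
    Bland-Altman limits of agreement with systematic-error rules, and
    percent agreement with qualitative rating scales.  A parametric
    synthetic hip-landmark generator with prescribed ground-truth
    morphology makes the whole pipeline testable without radiographs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
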