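Package: greenexp
Title: Activity-Space Greenspace Exposure, Physical Activity, and Health Mediation Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures individual daily greenspace exposure over activity
    spaces built from 24-hour activity diaries (time-weighted stay-point and
    travel-route buffers), scores weekly physical activity in IPAQ
    MET-minutes, and fits a maximum-likelihood structural equation model of
    greenspace exposure, physical activity, and physical, mental, and social
    health, including fit indices and direct/indirect/total effect
    decomposition. Ships a synthetic-cohort generator with a known latent
    ground truth so the full pipeline is testable end to end, plus planar
    geometry primitives (buffers, polygon intersection and union areas,
    nearest-feature distances) implemented in compiled code.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
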