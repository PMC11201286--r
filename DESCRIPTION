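Package: nmse
Title: Numerical Multi-Scoring System of Endometriosis (NMS-E)
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Preoperative endometriosis severity scoring with the Numerical
    Multi-Scoring System of Endometriosis (NMS-E). Computes component scores
    (ovarian cyst, tubal, adhesion, pain, uterine, rare-site) and the total
    E-score from transvaginal-ultrasound and pelvic-exam findings; renders
    the Physical Finding Map and a compact TNM-like summary notation with a
    round-tripping parser; reads and writes cohort CSV files; provides
    Spearman rank-correlation analysis with both the statistically standard
    average-rank tie handling and the spreadsheet minimum-rank dialect; fits
    and applies a linear surgical-duration predictor; scores and stages the
    revised ASRM classification for comparison; and simulates seeded
    synthetic patient cohorts with configurable marginals and target rank
    correlations via a Gaussian copula, so the analysis pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Matrix,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
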