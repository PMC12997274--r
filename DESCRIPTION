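Package: dp5q
Title: Quantile-Regression Shift Prediction and Absolute Confidence
    Scoring for Carbon NMR Structure Confirmation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts carbon-13 chemical-shift distributions with a
    quantile-regression graph neural network and converts them, together
    with an experimental peak list, into an absolute confidence (DP5q
    score) that a candidate structure is correctly assigned to the
    spectrum.  Includes dataset curation filters, a composite quantile
    loss with a crossing penalty, peak-to-environment assignment by
    optimal matching, conformer-ensemble prediction, and a synthetic
    benchmark harness for correct versus incorrect structure proposals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    ChemmineR
Suggests:
    testthat (>= 3.0.0),
    ChemmineOB,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
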