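Package: bpsignal
Title: Signal, Noise, and Power for Blood-Pressure Response Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for deciding whether office, home, and ambulatory daytime and
    nighttime blood-pressure responses to antihypertensive drug therapy measure
    one common signal, for decomposing each measurement method's variance into
    shared signal and method-specific noise, for constructing minimum-variance
    weighted-average responses from the inverse inter-method covariance matrix,
    and for computing the power and sample size needed to detect a genetic
    predictor of drug response under each measurement scheme.  Includes a
    synthetic-cohort generator calibrated to a pharmacogenomic monotherapy
    trial so that every stage of the pipeline can be exercised without
    subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
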