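Package: mrmpk
Title: Targeted LC-MS/MS Quantitation, Bioanalytical Method Validation and
    Noncompartmental Pharmacokinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates multiple-reaction-monitoring (MRM) plasma assays with
    known ground truth and carries the data through a complete bioanalytical
    workflow: chromatographic peak detection and integration with
    signal-to-noise estimation, response-ratio calibration with
    back-calculation and curve acceptance rules, the full FDA-style
    validation battery (accuracy, precision, recovery, matrix effect,
    dilution integrity, stability, selectivity), and non-compartmental
    pharmacokinetic analysis (Cmax, tmax, AUC by linear or linear-up/log-down
    trapezoid, terminal slope, half-life). Ships presets for a
    metformin/canagliflozin human-plasma assay and a reproducible pipeline
    runner with CSV/Markdown reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
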