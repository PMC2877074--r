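Package: tcscreen
Title: Time-Course Transcriptome Screening by Consecutive-Window Fold-Change Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for screening two-genotype, multi-time-point
    bead-array expression data for coherent differential expression.
    Implements chip-level quality control by inter-sample correlation
    clustering, per-tissue normalization, detection-call consecutive-presence
    filtering, floored genotype fold-change series, consecutive-window
    exceedance selection with an outside-window escape constraint,
    low-expressor classification, and run-length summary reporting.  Includes
    a synthetic bead-array generator with planted differential windows so
    every stage is testable against known ground truth, and a brute-force
    window-enumeration oracle for independent verification of the classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    limma,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
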