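Package: methylDx
Title: Copy-Number and Calibrated-Score Diagnostics for Methylation Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Diagnostic computation layer for DNA methylation array workup of
    CNS tumors. Calls copy-number variation from combined methylated plus
    unmethylated probe intensities against a flat-genome reference panel
    (genomic binning, minimal-MAD baseline, recursive binary segmentation,
    focal amplification and homozygous-deletion calling, IGV/SEG export),
    summarizes gain/loss frequencies across cohorts, interprets calibrated
    random-forest classifier scores with the methylation-class-family sum rule
    and a threshold ladder, runs batch quality control (sex concordance, CNV
    noise scoring, cross-contamination scanning, expectation consistency), and
    provides a three-state MGMT promoter methylation call through a pluggable
    two-probe logistic model. A synthetic-data generator produces reference
    panels, tumor arrays with known copy-number truth, purity and sex,
    contaminated mixtures, and calibrated score vectors so the full pipeline is
    exercisable without array data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
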