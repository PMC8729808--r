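Package: dualmeth
Title: Complementary Dual-Marker DNA Methylation Diagnostics from Array and MSP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and evaluation of a DNA methylation biomarker that
    complements an anchor gene in colorectal tumour detection. Computes
    CpG-island methylation levels (mean beta values) from Illumina 450k-style
    matrices, selects anchor-hypomethylated samples at the beta = 0.2
    threshold, ranks candidate complement genes genome-wide by their
    hypermethylation rate in that subset, and builds subsite-resolved rate
    tables. Interprets methylation-specific PCR (MSP) runs: ACTB validity
    gating, fixed Ct-cutoff calls, OR-combined dual-marker calls, and
    2^-ddCt relative methylation levels against a plasmid calibrator.
    Reports diagnostic performance (sensitivity, specificity, ROC AUC with
    DeLong confidence intervals, Youden-optimal cutoffs, Fisher and rank
    tests) stratified by bowel subsite, and ships a synthetic-cohort
    generator with the statistical structure of the tissue and stool study
    designs so the whole pipeline is testable without protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pROC,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
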