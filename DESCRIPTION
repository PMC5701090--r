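Package: mstrisk
Title: Microsatellite Genotyping and Case-Control Risk Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Toolkit for microsatellite (short tandem repeat) based
    case-control risk marker discovery and validation from targeted
    high-depth sequencing. Catalogs perfect tandem repeats in reference
    sequences, calls diploid repeat-tract-length genotypes from amplicon
    reads by exact flank anchoring with PCR-stutter filtering, screens
    loci for differing modal (control) and predominant (case) genotypes
    with Fisher exact tests under Benjamini-Hochberg false discovery
    rate control, builds fraction-of-risk-genotype classifiers with
    ROC-derived cutoffs, odds ratios and leave-one-out cross-validation,
    computes two-sample t-test power for cohort sizing, and simulates
    complete synthetic cohorts (reference, reads, genotypes) with a
    machine-readable truth manifest.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
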