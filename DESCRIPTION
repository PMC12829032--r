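Package: epihap
Title: Epiallele Analysis of Targeted Bisulfite Amplicon Sequencing in
    Prostate Needle Biopsies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-read methylation-pattern (epiallele) analysis of a single
    targeted bisulfite amplicon: read classification with noise filters for
    dimers, off-target alignments and incomplete bisulfite conversion;
    aggregation into the 0..K methylated-sites-per-strand spectrum; the
    highly-methylated-strand (7-8 of 8 CpG) biomarker score with
    Mann-Whitney and ROC/AUC group comparisons; qPCR standard-curve
    absolute quantification with reference-gene normalisation and
    calibrator scaling; COBRA restriction-digestion methylation estimates;
    and Yeo-Johnson-transformed robust regression of expression on
    methylation. Includes a synthetic-cohort generator (reads, metadata,
    qPCR plates) so the full analysis is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    car,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
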