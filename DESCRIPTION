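Package: tripet
Title: Multi-Tracer PET Lesion Phenotyping and Intermetastatic
    Heterogeneity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies co-registered multi-tracer PET volumes into
    per-lesion standardized-uptake-value (SUV) phenotypes and derives
    patient-level endpoints for metastatic castration-resistant prostate
    cancer imaging studies: threshold-based volume-of-interest
    segmentation against a liver reference, PERCIST-style SUVpeak ratios,
    FDG/PSMA/DOTATATE lesion positivity, intrapatient intermetastatic
    heterogeneity (IIH), and radiopharmaceutical-therapy eligibility
    flags.  Includes exact binomial prevalence estimation, two-group
    comparison tests, phenotype-stratified Kaplan-Meier / log-rank / Cox
    survival analysis, and synthetic phantom and cohort generators for
    fully reproducible end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    RNifti,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
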