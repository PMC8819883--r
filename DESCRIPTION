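Package: fetometab
Title: Non-Targeted LC-MS Metabolomics Pipeline for Germ-Free vs SPF Fetal
    Organ Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for non-targeted LC-MS metabolomics feature
    tables from a two-group (germ-free vs specific-pathogen-free) fetal mouse
    organ design: QC-based feature cleanup (detection rates, RSD*, D-ratio*
    with a classic-metric rescue clause), QC-anchored injection-order drift
    correction, random-forest imputation, per-organ differential abundance
    (pooled-variance t tests, Benjamini-Hochberg FDR, Cohen's d), SNR-based
    group-exclusivity calls and organ-wise Venn partitioning, t-SNE and
    k-means/hierarchical structure, MSI-level compound annotation against MSP
    libraries, and simplified mummichog-style m/z pathway enrichment. Includes
    a synthetic-data generator emulating the 6-dams-by-2-fetuses-per-group,
    three-organ, four-mode study design with planted ground truth so every
    stage is verifiable at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    ranger,
    Rtsne,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
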