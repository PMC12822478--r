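Package: crlmomics
Title: Proteogenomic Analysis of Colorectal Cancer Liver Metastasis Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, tested proteogenomic analysis pipeline for paired
    normal / primary tumor / liver metastasis (N/T/LM) multi-omics cohorts:
    TMT-style normalization and QC, copy-number cis-effect scans across
    mRNA/protein/phosphosite layers, layer-specific differential testing,
    metastasis signature construction with preranked GSEA and median
    signature scoring, kinase-substrate enrichment analysis (KSEA),
    consensus-clustering subtype discovery, downstream alternative-splicing
    analysis, Kaplan-Meier survival stratification, and cascaded biomarker
    nomination workflows. Ships a synthetic multi-omics cohort generator
    with planted, recoverable ground truth so every stage is testable
    without access to patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
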