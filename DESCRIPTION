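Package: methylmirror
Title: Cross-Tissue Differential DNA Methylation Analysis with Simulated
    Ground Truth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genome-wide analysis of Illumina 450k-style DNA methylation
    beta values across paired tissues (subcutaneous adipose tissue and
    circulating leukocytes) in obese versus non-obese groups: probe
    quality-control filtering, per-CpG Wilcoxon rank-sum testing with
    Benjamini-Hochberg false-discovery-rate control and delta-beta
    thresholds, genomic-context enrichment diagnostics, a cross-tissue
    concordant-signature selection cascade, hypergeometric gene-set
    over-representation, and ROC-based biomarker evaluation. A synthetic
    methylation-array generator with a planted-effect truth ledger makes
    every stage testable for power, false-discovery control and parameter
    recovery without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml
Config/testthat/edition: 3
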