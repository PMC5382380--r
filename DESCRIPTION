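Package: gxewas
Title: Gene-Environment Interaction Analysis for Methylation Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: End-to-end pipeline for epigenome-wide gene-by-environment
    interaction studies on Illumina 450K-style beta-value matrices: probe
    filtering and Greedycut-style quality pruning, beta/M transformation,
    principal-component batch diagnostics and location-based batch
    adjustment, Houseman-style reference-based leukocyte deconvolution,
    dual-model differentially methylated position (DMP) detection with an
    interaction-aware extreme-group filter, kernel-smoothed differentially
    methylated region (DMR) calling with Benjamini-Hochberg correction,
    DMP/DMR integration with Fisher-exact genomic, transcription-factor
    binding-site and gene-set enrichment, Baron-Kenny mediation with
    bootstrap indirect (ACME) effects, and targeted promoter-SNP and
    enzyme-activity models. Includes a synthetic-data generator with
    planted ground truth (DMPs, DMRs, cell mixtures, batch shifts, a
    cis-SNP-driven promoter cluster, mediated outcomes) so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    limma,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
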