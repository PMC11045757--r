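Package: domainsens
Title: Domain-Specific Inhibitor Screen Analytics and Spike-In Anchored
    Differential Expression
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for comparing domain-specific inhibitors of
    multidomain chromatin regulators (e.g. the EP300/CBP bromodomain
    inhibitor CCS1477 versus the HAT-domain inhibitor A485) across pooled
    cell-line viability screens, and for dissecting the transcriptional
    consequences of treatment with external spike-in controls. Provides
    dose-response AUC computation with per-compound median normalization
    and AUC-ratio classification; exon-union gene lengths and TPM;
    spike-in (ERCC) anchored MA-loess normalization that preserves global
    transcriptional shifts; a control-gene negative-binomial differential
    expression engine with median-of-ratios size factors restricted to
    spike-in rows; integration of drug-downregulated gene sets with
    CRISPR gene-effect (Chronos-style) dependency screens via Fisher
    exact tests and interaction-network connectivity; k-means clustering
    with elbow-based k selection, hypergeometric gene-set enrichment and
    E-box (CACGTG) promoter motif scanning. Includes seed-deterministic
    simulators for every input so the full pipeline is testable against
    known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    Biostrings,
    IRanges,
    GenomicRanges,
    igraph,
    fgsea,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    DESeq2,
    jsonlite,
    optparse
Config/testthat/edition: 3
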