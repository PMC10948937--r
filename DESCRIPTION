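Package: dmrscape
Title: Cross-Platform Differential DNA Methylation Analysis for Brain Tumor Epigenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for multi-platform DNA methylation analysis of
    pediatric brain tumors (AT/RT, medulloblastoma, choroid plexus tumors):
    differentially methylated region (DMR) calling on methylation-array probes
    and bisulfite-sequencing tiles, control-comparison filtering, extraction of
    cancer-specific hyper/hypomethylated region sets, transcription-factor
    binding-site enrichment with categorized catalogs and co-localization,
    detection of TAD-scale large methylation shifts, categorization of DMRs
    against pluripotent stem cell and fetal brain methylomes, integration of
    differential methylation with differential expression (DM-DE genes), and
    CUT&RUN peak filtering with position-weight-matrix motif scanning. Includes
    a synthetic-study generator with machine-readable ground truth for every
    planted signal, so the whole pipeline is exercised end-to-end with known
    answers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
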