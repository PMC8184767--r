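Package: scregulome
Title: Integrated Single-Cell Chromatin Accessibility and Expression Analysis of Root Cell Types
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for joint analysis of single-cell ATAC-seq and
    single-cell RNA-seq data from complex tissues such as the Arabidopsis
    thaliana root. Implements gene-activity scoring from peak-level cut
    counts, distal/proximal peak classification, cell-type-specific
    differential accessibility, linear regression of relative peak
    accessibility on transcription-factor motif content with family-level
    summaries, k-nearest-neighbor transfer of expression-derived features
    across modalities in a joint embedding, two independent
    endoreduplication (ploidy) classifiers, transcriptional-complexity
    metrics of developmental progression, and regression linkage of peak
    accessibility to transcription-factor expression with opening/closing
    classification and binned pseudo-bulk tracks. A synthetic multiome
    generator with planted ground truth supports parameter-recovery testing
    of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
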