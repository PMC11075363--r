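Package: placentomics
Title: Multi-Omic Analysis of Trophoblast Development and Placental
    Epigenetics in Preeclampsia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the bespoke computational procedures of a multi-omic
    placenta study of preeclampsia: differentially methylated region (DMR)
    calling by merge/seed/circular-binary-segmentation/k-means, trophoblast
    maturity classification from RNA-velocity latent time and CytoTRACE
    scores, maternal/fetal origin scoring via bin-matched module scores,
    imprinted-gene dosage direction analysis, identification of virus-like
    particle cargo genes (expressed yet chromatin-silent in receiver cells)
    with allele-of-origin tracing and UTR motif similarity, and broad
    histone-domain differential statistics with region-overlap enrichment.
    A synthetic-data module generates every input with planted ground truth
    so each stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    Matrix,
    Rcpp,
    IRanges,
    GenomicRanges,
    Biostrings,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
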