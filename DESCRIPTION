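Package: nucperi
Title: Nuclear-Periphery Enrichment and Chromatin Interval Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analyses for studies of interphase heterochromatin
    at the nuclear periphery. Implements exact genomic-interval algebra with
    control-peak subtraction and replicate-consensus operators,
    subtelomeric-window fold-enrichment with permutation and binomial nulls,
    gene-feature annotation and pairwise histone-mark co-occurrence with
    exact tests, equal-area erosion-shell radial positioning of loci in
    nucleus masks, a line-profile peripheral-enrichment statistic,
    spot/foci detection and quantification, and synthetic-data generators
    with recoverable ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
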