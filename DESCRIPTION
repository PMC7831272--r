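Package: acetylink
Title: Differential H3K27ac ChIP-Seq and RNA-Seq Integration with
    Correlation-Based Enhancer-Gene Linking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for integrating H3K27ac ChIP-seq with
    RNA-seq in a two-group replicated design, as applied to fatty liver
    hemorrhagic syndrome in laying hens. Provides summit-distance peak
    merging, length- and depth-normalized input-subtracted acetylation
    quantification, a self-contained negative-binomial Wald test for
    differential acetylation and expression with Benjamini-Hochberg
    correction, Pearson-correlation linking of differential peaks to
    candidate target genes within 1 Mb, PWM motif enrichment and
    hypergeometric gene-set over-representation, delta-delta-Ct qPCR
    arithmetic, and a seeded synthetic-data generator with planted
    differential and link structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
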