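Package: rnadel
Title: DNA-Encoded Library Versus RNA Fold Library Screening Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational pipeline for screens that cross a DNA-encoded
    small-molecule library (DEL) against an RNA secondary-structure fold
    library. Provides combinatorial enumeration of a split-pool DEL with a
    Hamming-separated DNA barcoding scheme; decoding of sequencing reads
    from sorted beads into compounds with replicate (k-class) counting,
    two-channel selectivity filtering and Tanimoto leader clustering;
    enrichment analysis of selected RNA folds against the starting library
    via a pooled two-proportion z statistic with privileged-fold calling,
    sequence logos and difference logos; mining of privileged internal-loop
    motifs across microRNA hairpins with Drosha/Dicer processing-site
    annotation and expression-weighted target ranking; and synthetic-data
    generators with planted ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
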