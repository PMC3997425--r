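Package: hexamir
Title: Small RNA Discovery and Expression Profiling for Hexaploid Wheat
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end small RNA analysis pipeline for hexaploid wheat
    and other plants lacking a finished reference genome. Implements a read
    elimination pipeline (adapter trimming, length, low-complexity, invalid
    and t/rRNA filters, collapsing to unique reads), exact genome mapping on
    both strands, hairpin-based miRNA prediction under community (Meyers)
    annotation criteria with star-strand calling, classification of mature
    sequences against a miRBase-style catalog into known, variant, true
    novel and candidate novel categories, tags-per-million digital
    expression with fold-change selection, Venn partitioning and
    uncentered-Pearson average-linkage clustering, and
    complementarity-based miRNA target prediction with cleavage-site
    inference. Ships a seeded synthetic-data generator that emulates an
    eight-library tissue/stress study design so the whole pipeline can be
    exercised and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    ape,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
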