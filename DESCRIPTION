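Package: neorfpop
Title: Expression and Coding Potential of Newly Evolved ORFs in Pooled
    Population RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for studying newly evolved open reading
    frames (neORFs, de novo gene candidates) in pooled population RNA-seq
    data from Drosophila melanogaster. Provides TPM-based expressed-gene
    calling with orthogroup aggregation, negative-binomial differential
    expression with Benjamini-Hochberg FDR control and independent
    filtering, gene-class enrichment statistics, a two-step read-pair
    classifier of ORF integrity (cat1-cat5 / catA-catE), Nei-Gojobori
    pN/pS estimation from pooled reads with read-support thresholds,
    line-frequency-class enrichment analysis, genome-placement filtering
    with 1-kb neighbor-gene association tests, and a forward simulator
    that generates annotations, pooled count matrices, read-pair
    alignments and polymorphic read pools with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    GenomicAlignments,
    IRanges,
    purrr,
    readr,
    rlang,
    Rsamtools,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
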