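Package: pcrscore
Title: Primer Design and Evaluation for Multiple PCR Variants by
    Piecewise Logistic Scoring
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: High-throughput design and evaluation of PCR primers for
    generic, genotyping, ARMS, inverse (back-to-back) and anchored
    (unidirectional) PCR, and fully-covered tiling panels. Every primer
    feature (melting temperature, GC content, self-complementarity,
    3' end adenines, 3' end stability, common SNPs and homopolymer
    runs) and every pair relation feature is scored with a piecewise
    logistic model, and the highest-scoring pairs are always returned
    instead of failing on hard parameter filters. Specificity is
    evaluated by enumerating all target and non-target products on a
    reference sequence with a 7-mer seed-and-extend search and
    predicting the amplification efficiency of every product from
    bound melting temperature, mismatch positions and product size.
    Includes nearest-neighbor thermodynamics, degenerate-base masking
    of common variants, multiplex cross-dimer screening, and a
    seeded synthetic fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    data.table,
    methods,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
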