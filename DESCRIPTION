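Package: estssr
Title: EST-SSR Marker Development Toolkit
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Develops simple sequence repeat (SSR) markers from expressed
    sequence tags (ESTs). Cleans raw transcript FASTA files (poly-A/T
    trimming, length filtering, contaminant screening, greedy identity
    clustering), detects perfect and compound microsatellites under
    configurable criteria presets with canonical motif classification,
    designs and scores flanking PCR primer pairs with optional M13 tailing,
    places loci on a reference genome from tabular alignment hits and
    classifies them into CDS/UTR regions, computes per-locus diversity
    statistics (allele number, expected heterozygosity, polymorphism
    information content) and a polymorphism-versus-repeat-count logistic
    regression, builds bootstrap-supported neighbor-joining trees from
    cross-species transferability matrices, and tests GO-term
    overrepresentation with Fisher's exact test under Benjamini-Hochberg
    false discovery rate control. Seeded synthetic-fixture generators
    emulate every input format with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
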