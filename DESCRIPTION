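Package: plantKinome
Title: Plant Kinome Cataloguing, Duplication, Selection and Expression Analysis
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-wide protein kinase (kinome) studies in plants:
    kinase candidate identification from Pfam domain hits and family HMM hit
    tables, neighbor-joining trees with bootstrap support and a
    tree-concordance (bona fide/UNK) filter, per-gene structural features and
    protein pI/MW, MCScanX-style duplication-origin classification with
    collinear (syntenic) block detection, pairwise Ka/Ks by the Nei-Gojobori
    method with Jukes-Cantor correction, promoter extraction with JASPAR PWM
    scanning and hypergeometric cis-element enrichment, differential-expression
    filtering with GO enrichment and crosstalk summaries, and qPCR relative
    expression ratios with a label-reallocation randomization test. A seeded
    synthetic-genome generator with machine-readable ground truth makes every
    stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    ape
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    igraph,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
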