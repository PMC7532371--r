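Package: cmtnet
Title: Gene-Set Enrichment, Term Crosstalk and MCODE Module Detection for Disease Gene Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A reusable systems-biology pipeline for curated disease gene
    sets, motivated by network analyses of Charcot-Marie-Tooth disease genes.
    Provides over-representation analysis against GMT annotation databases
    (one-sided hypergeometric test with Benjamini-Hochberg FDR control),
    construction of a biological-process crosstalk network scored by the
    average of Jaccard and Overlap coefficients with explicit term and pair
    filters, seed-centred first-neighbour expansion of an interactome, a
    from-scratch implementation of the MCODE molecular-complex detection
    algorithm with haircut and fluff post-processing, extraction of non-seed
    candidate genes from top-ranked clusters, and a synthetic-data generator
    with known ground truth (enriched terms, planted dense modules) so every
    stage is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
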