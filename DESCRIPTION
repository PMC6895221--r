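Package: sigcarcin
Title: Consensus Somatic Variant Calling and Mutational Signature Analysis
    for Carcinogen-Induced Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for characterizing the somatic mutanome of
    small carcinogen-induced tumor cohorts. Reads per-caller somatic VCFs and
    applies an m-of-n consensus vote followed by germline-panel and
    shared-across-cohort filters; builds SBS-96 trinucleotide-context mutation
    catalogs and transcriptional-strand-resolved SBS-192 catalogs with exact
    binomial strand-bias tests; extracts de novo mutational signatures by
    bootstrapped non-negative matrix factorization with silhouette-based
    stability selection of the rank; and scores extracted signatures against a
    reference signature matrix by cosine and Pearson similarity. Ships a
    self-contained synthetic cohort generator (genome, gene models, planted
    signature mixtures with transcriptional strand bias, imperfect callers,
    germline contamination) so that the whole pipeline can be exercised and
    validated without external data.
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
    GenomeInfoDb,
    rtracklayer,
    vcfR,
    cluster,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
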