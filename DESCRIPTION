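Package: mirEST
Title: Homology-Based Discovery of MicroRNAs, Their Precursors, Targets
    and Polymorphisms in EST Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for homology-based identification of
    plant microRNAs in expressed sequence tag (EST) collections. Mature miRNA
    reference sets are scanned against ESTs with a deterministic
    mismatch-limited search in both orientations; per-species representation
    is assessed with an exact binomial statistic; candidate pre-miRNA hairpins
    are extracted around sense hits, folded with a bundled nearest-neighbour
    minimum-free-energy engine and screened on MFEI and miRNA/miRNA* duplex
    criteria; antisense target sites are profiled position-by-position in
    miRNA coordinates; EST clusters are assembled into consensus alignments
    from which SNPs and indels at miRNA-relevant positions are called and,
    for precursor variants, re-folded to estimate the folding impact (delta
    delta G). A synthetic-data generator with a machine-readable ground-truth
    manifest makes every stage testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
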