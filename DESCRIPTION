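Package: saltmir
Title: Small RNA Read Clustering, Hairpin Discovery and miRNA Key-Gene
    Ranking for Multi-Treatment Stress Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained small-RNA analysis chain for plant stress
    experiments: 3' adapter trimming, size and contaminant filtering, read
    collapsing and exact genome placement; greedy positional read clustering
    into miRNA arm candidates and pairing of same-strand clusters into
    hairpin candidates; a base-pair-maximisation fold screen of candidate
    precursors; count normalisation and Fisher-exact differential expression
    across a four-treatment design (control, NaCl, NaCl+thiourea, thiourea);
    plant miRNA target-site expectation scoring with inhibition-mode
    classification; and Pearson coupling plus ranking of target genes to
    nominate key genes of redox-mediated salt tolerance. A synthetic-data
    module plants ground-truth hairpins, treatment-structured libraries and
    coupled or decoupled target transcripts so every stage is verifiable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    rtracklayer,
    BiocGenerics
Config/testthat/edition: 3
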