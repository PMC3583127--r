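Package: affipair
Title: Prediction of Interacting Transcription Factor Pairs from Promoter
    Binding Affinity
Version: 0.1.0
Authors@R:
    person("affipair", "developers", email = "affipair@example.org",
           role = c("aut", "cre"))
Description: Predicts cooperating transcription factor (TF) pairs from
    sequence alone. Promoters are scored against JASPAR-style position
    weight matrices with a biophysical (TRAP-like) occupancy model, each
    TF's promoters are ranked by affinity, and every TF pair is scored by
    the minimum hypergeometric overlap p-value over a grid of top-list
    cutoffs. A motif-similarity filter removes pairs whose overlap is an
    artifact of near-identical binding motifs, and a partial-independence
    G-test on 2x2x2 contingency tables couples shared top targets with
    tissue-specific gene sets to call tissue-specific interactions.
    Includes network construction with hub detection and enrichment of
    known protein-protein interactions, a seeded synthetic-fixture
    generator with planted co-occurring motifs for end-to-end validation,
    and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
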