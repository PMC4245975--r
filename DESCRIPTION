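Package: mirdetox
Title: Off-Target Prediction and Seed Redesign for RNAi Guide Strands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Seed-mediated off-target analysis and repair for artificial
    miRNA / shRNA guide strands. Implements canonical (8mer, 7mer-m8,
    7mer-A1, 6mer) and relaxed (mismatch/G:U-tolerant) seed-site scanning of
    3'UTR collections, nearest-neighbor duplex hybridization energies, target
    site accessibility (opening) energies and the resulting delta-delta-G
    site score, a simplified context-like site score, gene-level off-target
    profiling with expression filtering and cross-species conservation,
    single-nucleotide seed-variant design with exclusion rules and ranking,
    seed-preserving retargeting of a guide against a new transcript, and a
    deterministic synthetic-data generator with planted ground truth for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
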