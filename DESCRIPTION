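Package: reosig
Title: Rank-Based Gene-Pair Signatures Robust to Degraded RNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and applies qualitative transcriptional signatures based on
    within-sample relative expression orderings (REOs) of gene pairs, designed to
    tolerate the zero-inflated, degraded expression profiles typical of FFPE
    clinical material. Provides the core REO machinery (stable and significantly
    reversed gene pairs with hypergeometric testing and FDR control, retention
    rates), a many-pair early-diagnosis classifier built by rank-difference
    scoring with redundancy removal, a RankComp-style rank-based differential
    expression caller, a relapse-risk signature built from DEG-anchored reversed
    pairs with coverage-difference ranking and paired FF/FFPE concordance
    filtering, survival evaluation of predicted risk groups, and a fully seeded
    synthetic cohort generator with planted ground truth for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
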