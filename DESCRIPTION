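Package: tanifish
Title: Ligand-Based Target Fishing with Tanimoto Similarity Thresholds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Similarity-centric target fishing: curate a ligand-target
    bioactivity reference library, rank candidate protein targets for a
    query molecule by Tanimoto nearest-neighbour scoring (MaxTc, KNNTc,
    MeanTc) over multiple 2D fingerprints, fuse fingerprints by z-score or
    rank-sum ensembles, and calibrate fingerprint-specific similarity
    thresholds (true-positive onset and F1-optimal) with precision/recall
    sweeps, binned precision profiles and enrichment-rate statistics.
    Includes a scaffold-stratified leave-one-out-like cross-validation
    harness and a seeded synthetic fixture generator for end-to-end
    testing without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
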