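Package: decrange
Title: Dispersal-Extinction-Cladogenesis Ranges and Highland-Lowland
    Transition Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for historical biogeography on fossil-calibrated time
    trees: a maximum-likelihood dispersal-extinction-cladogenesis (DEC)
    engine with adjacency-constrained range states, per-node ancestral
    split scenarios, inference of the polarity and timing of biogeographic
    transitions between highland and lowland regions (Andes and Amazonia),
    summary statistics for a curated compendium of dated transitions,
    alignment-level diagnostics (site masking, uncorrected-p distances,
    base-composition heterogeneity, parsimony signal), and seeded
    simulators for ultrametric trees, geographic range histories, and
    GTR+Gamma alignments.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    phangorn,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
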