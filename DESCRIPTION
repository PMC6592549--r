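Package: modelrank
Title: Ligand-Guided Ranking of GPCR Homology-Model Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores ensembles of aminergic G-protein coupled receptor homology
    models by the fraction of docked ligand poses that form the hallmark
    charged interaction with the conserved binding-site aspartate (D3.32),
    ranks the models, and localizes the side-chain conformations that
    discriminate the best from the worst scoring models via per-atom
    differences of group mean structures.  Includes rigid-body superposition
    with backbone/side-chain RMSD decomposition, a ChEMBL-style bioactivity
    curation and deduplication pipeline with MaxMin diversity picking and
    Cheng-Prusoff utilities, a synthetic fixture generator that emulates
    modelling and docking outputs with known ground truth, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    ChemmineR,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
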