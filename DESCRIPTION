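Package: phoregen
Title: Topological Pharmacophore Fingerprints and Pharmacophore-Conditioned
    SMILES Generation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Interpretable two- and three-point topological pharmacophore
    fingerprints (72/108/1032 bits) built on eight feature families, a
    pharmacophore-conditioned autoregressive SMILES decoder with rotary
    positional encoding, scaffold-elaboration sampling, evaluation metrics
    for pharmacophore-constrained generation (feature-count deviation,
    structural and pharmacophoric similarity, recall), and the
    scaffold-clustered splitting and virtual-screening triage procedures
    used to prioritise generated molecules. Chemistry primitives are
    provided by OpenBabel via ChemmineOB.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    igraph,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
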