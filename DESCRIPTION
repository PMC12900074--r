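Package: dyneff
Title: Conformational-Ensemble Graph Learning for GPCR Ligand Efficacy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies G protein-coupled receptor (GPCR) ligands as agonists
    or nonagonists from multi-conformation receptor ensembles. Implements
    residue-residue contact scoring (RRCS) and its reference-normalized form
    for per-frame activation-state calls and representative-conformation
    selection, Kabsch alignment and principal component analysis of C-alpha
    coordinates, heterogeneous protein-ligand complex graphs with geometric
    and structural edge channels, an E(3)-equivariant message-passing scorer
    with penultimate-feature extraction, a multi-conformation transfer-learning
    classification head, ensemble-docking baselines, scaffold-aware
    cross-validation splits, and a seeded synthetic-data suite so the whole
    workflow runs end to end without external structures or docking software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    readr
Config/testthat/edition: 3
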