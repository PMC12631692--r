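Package: molgat
Title: Small Graph Attention Networks for Molecular Property Regression
    with SMILES-Positional Readout
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Regression of scalar molecular properties (aqueous solubility,
    hydration free energy, lipophilicity, enzyme inhibition) from SMILES
    strings with a deliberately tiny graph attention network (about 3.7
    thousand parameters). Each heavy atom carries 14 atomic features plus 21
    molecule-level descriptors (15 chemical, 6 conformer-derived geometric)
    broadcast to every node, and the molecular prediction is read from a
    single SMILES-position-selected node rather than, or alongside, global
    pooling. Includes dataset loaders for the MoleculeNet CSV dialects, a
    deterministic OpenBabel-based featurizer, hand-written GAT/GATv2/GCN
    layers trained with RMSprop, node-position and feature-ablation reports,
    a random-forest descriptor baseline, k-fold cross-validation, and a
    synthetic-data generator for end-to-end testing without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    randomForest,
    stats
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: OpenBabel (obabel on the PATH)
Config/testthat/edition: 3
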