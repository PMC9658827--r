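Package: mdcontact
Title: Interface Contacts in Docking Ensembles and Molecular Dynamics Replicates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Nominates candidate protein-protein interaction residues for a
    two-chain complex. Ranks docking ensembles by the number of hydrogen bonds
    crossing the chain interface, analyses molecular-dynamics trajectory
    replicates for per-residue contact persistence and center-of-mass distance
    statistics, and aggregates replicates into residue prevalence tiers.
    Includes a seeded synthetic-data generator producing two-chain complexes,
    docking ensembles with planted interface hydrogen bonds, and trajectory
    replicates with planted contact probabilities and distance distributions,
    so every stage can be validated against known ground truth.
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
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
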