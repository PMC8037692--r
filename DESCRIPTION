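Package: mcrpharm
Title: Multicomponent-Reaction Library Design and Pharmacophore Screening Workbench
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico workbench for scaffold-focused antagonist design built
    around multicomponent reactions (MCR). Enumerates Ugi three-component and
    Ugi-tetrazole combinatorial libraries from role-labelled building blocks,
    profiles the products (physicochemical descriptors, MACCS/Tanimoto diversity
    embedding, silhouette-guided k-means clustering, principal-moment shape
    analysis, extended rule-of-five), expands compounds into ranked conformer
    sets, builds ensemble consensus pharmacophores from aligned ligand
    collections and screens conformers against them, analyses docking poses
    (substructure-anchored RMSD, match frequencies, pocket selectivity, pose
    clustering), post-processes molecular-dynamics trajectories (RMSD/RMSF,
    binding-site water occupancy, ligand residency, interaction fingerprints)
    and aggregates MM/PBSA-style energy tables. Ships seeded synthetic-data
    generators so every stage can be exercised end-to-end without external
    datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    bio3d,
    Biostrings,
    cluster,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: OpenBabel command-line tools (obabel, obenergy) on PATH
Config/testthat/edition: 3
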