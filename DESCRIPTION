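Package: ligdyn
Title: Docking-Ensemble and Trajectory Analysis of Protein-Ligand Binding Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit for characterising protein-ligand complexes from
    docking ensembles and molecular-dynamics trajectories. Implements the Pnear
    funnel-quality statistic over score-versus-RMSD docking ensembles, geometric
    interaction fingerprints (hydrogen bonds, salt bridges, hydrophobic contacts,
    pi-stacking) with persistence statistics, grid-based binding-pocket volume
    tracking, essential-dynamics principal component analysis of C-alpha
    fluctuations, DBSCAN conformational clustering on pairwise RMSD, furanose
    pseudorotation (sugar pucker) classification, and aggregation of per-residue
    energy-decomposition tables. Ships ground-truth synthetic-data generators so
    the whole pipeline is testable end to end without external simulation data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    bio3d,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
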