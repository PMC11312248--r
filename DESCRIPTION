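Package: ShapePharm
Title: Shape-Focused Pharmacophore Models from Docked Ligand Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds cavity-filling, shape-focused pharmacophore models by
    graph clustering the overlapping atoms of flexibly docked active-ligand
    poses, either by greedy shortest-pair merging with atom-type-specific
    search radii or by native Markov clustering on squared-distance
    similarities. Screened poses are scored against a model by Gaussian-volume
    shape similarity and smoothed-charge electrostatic correlation, in fixed
    (rescoring) or rigid-body-aligned (rigid docking) mode. Includes virtual
    screening enrichment metrics (ROC AUC with Wilcoxon error, enrichment
    factors at decoy fractions, BEDROC, semilogarithmic ROC curves),
    enrichment-driven greedy model optimization by single-atom deletion, a
    synthetic docked-pose benchmark generator, and a command-line interface.
    Molecules are read and written as multi-entry Sybyl TRIPOS MOL2 files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'cutoffs.R'
    'mol2-io.R'
    'config-io.R'
    'input-prep.R'
    'clustering.R'
    'mcl.R'
    'model-post.R'
    'similarity.R'
    'rigid-dock.R'
    'enrichment.R'
    'optimize.R'
    'fixtures.R'
    'pipeline.R'
    'cli.R'
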