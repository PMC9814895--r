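Package: hydrascore
Title: Hydration-Aware Voxel Featurization, Pose Scoring and Relevance
    Analysis for Protein-Ligand Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for hydration-aware scoring of protein-ligand binding
    poses. Rasterizes typed protein and ligand atoms into multi-channel
    voxel images, converts explicit-water trajectories with per-water
    interaction energies into occupancy, enthalpy and entropy grids
    (grid-based pseudo-hydration-site analysis in the GIST/WATsite
    lineage), trains a small 3D convolutional pose classifier with a
    combined classification and contact-mode-score loss, explains its
    predictions with deep-Taylor layer-wise relevance propagation
    (z-plus rule), and evaluates poses with symmetry-aware RMSD,
    solvent-exposure-modified RMSD and contact mode scores. Includes a
    synthetic-data generator with planted hydration hotspots so the
    whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    ChemmineR,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
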