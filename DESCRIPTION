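Package: groovescope
Title: pH-Dependent Electrostatics and Groove Plasticity of Lipid-Antigen-Binding Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for pH-dependent plasticity of lipid-antigen-binding
    grooves such as the CD1d portal. Combines multi-predictor pKa tables by a
    consensus rule, assigns protonation states and formal side-chain charges at
    arbitrary pH, solves the linearized Poisson-Boltzmann equation on focused
    finite-difference lattices with OpenDX output, detects binding-site cavities
    on a 3D lattice and tracks their volume and per-voxel occupancy across
    trajectory frames, computes Gaussian-network-model normal modes with
    per-chain amplitude profiles, and measures groove geometry (portal aperture,
    helix bending, RMSD traces, RMSD-based multidimensional scaling). Includes
    deterministic synthetic-structure generators (portal scaffolds, breathing
    trajectories, cavity probes, protonation scenarios) for end-to-end testing
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
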