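Package: trajan
Title: Analysis of Molecular Structures, Trajectories, and Free-Energy
    Surfaces
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Toolkit for coarse-grained analysis of molecular structures
    and molecular-dynamics trajectories.  Reads PDB structures
    (including multi-model files) and CHARMM/X-PLOR binary DCD
    trajectories, resolves slash-style atom selections, and provides:
    Calpha elastic network models (linear-cutoff and distance-dependent
    Kovacs force constants) with normal modes, structural perturbation
    analysis, theoretical B-factors, involvement coefficients and
    mode-based residue correlations; dynamic cross-correlation and
    linear mutual information of atomic fluctuations; protein structure
    networks with interaction strengths, hubs, node clusterization,
    critical interaction strength and trajectory stability statistics;
    shortest non-covalent communication paths filtered by motion
    correlation; conformational clustering (leader-like, hierarchical,
    quality-threshold-like) on RMSD or DRMS with two-pass refinement
    and distance-matrix persistence; and free-energy-surface analysis
    of microstate timeseries via transition networks, analytic
    committor probabilities and mean first passage times, cut-based
    free-energy profiles and kinetic grouping into basins.  Seeded
    synthetic-data generators produce every fixture needed for
    validation.
License: GPL (>= 3)
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
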