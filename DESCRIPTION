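Package: lipidgate
Title: Binding-Pocket Occupancy, Gating-Residue Dynamics and Pre-Reactive
    Geometry in Lipid-Hydrolase MD Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-processing toolkit for molecular dynamics trajectories of
    lipid-hydrolysing enzymes with multi-pocket active sites, built around the
    fatty acid amide hydrolase (FAAH) membrane-access / acyl-chain-binding
    channel system. Computes per-frame minimum distances from a substrate
    acyl-chain tail to configurable residue groups and assigns pocket occupancy
    states (MA/T/AB/not-bound), classifies acyl-chain conformations in the
    Applegate-Glomset taxonomy (elongated/hooked/curved and fine classes) from
    backbone torsion profiles or end-to-end geometry, tracks the chi1-like
    gating dihedrals of dynamic-paddle residues and their open/closed states,
    detects pre-reactive (near-attack) conformations from configurable
    geometric criteria, and aggregates equilibration-aware occupancy
    statistics, cross-tabulations, transfer counts and per-monomer pooling.
    Includes a seeded synthetic-trajectory generator with Markov pocket-hopping
    ground truth for validation, and Michaelis-Menten and competition-assay
    exponential-decay fitting with selectivity ratios. All tabular results are
    tibbles; fitted objects support tidy() and glance().
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
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
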