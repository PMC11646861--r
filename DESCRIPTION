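Package: allonet
Title: Dynamic Residue-Interaction Networks and Generalized Correlation
    Analysis for Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-simulation analysis of molecular dynamics trajectories of
    membrane receptors and other proteins: conformational readouts (RMSD,
    RMSF, single-linkage conformational clustering, side-chain dihedrals,
    minimum inter-residue distances), geometric protein-ligand interaction
    profiling (hydrogen bonds, hydrophobic contacts, salt bridges with
    per-frame interaction probabilities), grid-based binding-pocket volume
    inside a fixed maximum-englobing region, generalized correlation
    coefficients from Kraskov k-nearest-neighbour mutual information, and
    contact-filtered correlation-weighted dynamic networks (betweenness and
    eigenvector centralities, knee thresholds, optimal communication paths).
    Includes seed-deterministic synthetic-trajectory generators with known
    ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
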