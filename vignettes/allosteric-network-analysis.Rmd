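---
title: "Dynamic residue-interaction networks from MD trajectories: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic residue-interaction networks from MD trajectories: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allonet)
```

## Scope and model

`allonet` analyses molecular-dynamics trajectories of proteins — it was
written with seven-transmembrane (7TM) receptors in mind — after the
simulation has been run elsewhere. The pipeline has five stages:

1. **Conformational readouts.** RMSD against a reference frame after Kabsch
   superposition, per-residue RMSF about the time-averaged structure,
   single-linkage clustering of frames on a pairwise-fitted backbone RMSD
   matrix, signed side-chain dihedrals, and minimum inter-residue distances
   (minimum-image when a periodic cell is present).
2. **Geometric interaction profiling.** Hydrogen bonds, hydrophobic
   contacts and salt bridges detected per frame from explicit-hydrogen
   geometry, summarised as per-pair interaction probabilities (fraction of
   frames in which the interaction is present).
3. **Pocket volume.** Grid occupancy inside a fixed maximum-englobing
   region (MER): a sphere, conventionally of radius 1.3 nm centred on the
   bound ligand's mass centroid in a defining frame, with per-atom van der
   Waals exclusion spheres.
4. **Generalized correlations.** For every residue pair, the mutual
   information `I` between the two alpha-carbon position samples is
   estimated with the Kraskov k-nearest-neighbour estimator and mapped to
   the generalized correlation coefficient
   `r_MI = sqrt(1 - exp(-2/3 I))`, which lies in [0, 1] and captures
   non-linear as well as linear coupling. For jointly Gaussian 3-D
   variables with per-axis correlation `rho`, `I = -(3/2) log(1 - rho^2)`
   and hence `r_MI = |rho|` exactly — this identity is the package's main
   correctness oracle.
5. **Dynamic network.** Nodes are residues (alpha-carbon sites; a ligand
   contributes one node at the heavy atom nearest its mass centroid).
   An edge joins two nodes when their heavy-atom contact frequency (minimum
   distance below 0.45 nm) is at least 0.75 — the threshold is inclusive —
   and carries weight `w = r_MI` with derived length `l = -log(w)`.
   The network is characterised by node/edge betweenness (normalised by
   `2/((n-1)(n-2))` and `2/(n(n-1))` respectively), eigenvector centrality
   of the weighted adjacency, knee-thresholded centrality distributions
   grouped by transmembrane segment, and optimal source-to-target
   communication paths.

## Parameters that matter

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| Kraskov `k` | 6 | neighbours | conventional choice for residue-pair generalized correlations |
| correlation stride | 1000 | ps | successive analysed frames should be decorrelated |
| general sampling | 50 | ps | default frame spacing assigned on load |
| contact cutoff | 0.45 | nm | heavy-atom contact definition for network edges |
| contact frequency cutoff | 0.75 | fraction | inclusive edge-formation threshold |
| cluster RMSD cutoff | 0.1 | nm | scale of one GPCR conformational basin (backbone atoms) |
| MER radius | 1.3 | nm | orthosteric-pocket englobing sphere |
| pocket grid spacing | 0.05 | nm | < 2% volume error on the analytic phantom at seconds per frame |
| H-bond | 0.41 nm, 100° | | published PLIP geometric defaults |
| hydrophobic | 0.40 | nm | PLIP default carbon-carbon cutoff |
| salt bridge | 0.55 | nm | PLIP default centroid separation |

All criteria are config-overridable through `interaction_criteria()`,
`kraskov_params()` and `define_mer()`.

## The Kraskov estimator: algorithm choice and bias

Two renderings of the k-nearest-neighbour MI estimator circulate: algorithm
1, `I = psi(k) - <psi(n_x + 1) + psi(n_y + 1)> + psi(N)` with marginal
counts strictly inside the k-th joint-neighbour distance, and algorithm 2,
which subtracts `1/k` and counts within per-marginal distances. `allonet`
implements algorithm 1 with the max-norm across the two 3-D marginal blocks
and the Euclidean norm inside each block; neighbour search is exact (brute
force in compiled code), so estimates are deterministic given the input.
Raw estimates can dip slightly below zero near independence and are clamped
at zero before the `r_MI` transform, which is undefined for negative `I`.

Like every kNN density-ratio estimator, this one is biased downward at
strong dependence and finite `N`: at `rho = 0.8`, `N = 1200`, `k = 6` the
measured mean is about 1.33 nats against the closed-form 1.53 (the same
value is obtained from an independent re-implementation, and the gap
shrinks as `N` grows or `k` falls — the package's consistency tests check
exactly this). The `r_MI` transform compresses that bias: mean recovered
`r_MI` is within ±0.07 of the true `rho` across `rho` from 0 to 0.9 at
`N = 1200`. Conclusions should therefore be drawn on the `r_MI` scale, and
between-state differences (`delta_matrix()`) are more trustworthy than
absolute MI values. The diagonal of a correlation matrix is fixed at 1
(self-MI diverges).

## Network conventions

* **Path objective.** "Most correlated path" is ill-posed as a literal sum
  of correlations: longer paths accumulate more terms. The default
  objective maximises the *product* of edge correlations, i.e. minimises
  `sum(-log w)` — the standard correlation-network convention, solved by
  Dijkstra. The literal sum objective is available
  (`optimal_path(mode = "sum")`) with an explicit hop bound.
* **Degenerate shortest paths.** Brandes accumulation splits counts across
  equal-length paths; with continuous correlation weights, exact float ties
  essentially never occur, and the underlying graph library's deterministic
  traversal fixes any residual ambiguity.
* **Knee thresholds.** Rank-value curves of centralities are thresholded at
  the point of maximum perpendicular distance from the chord joining the
  first and last rank — deterministic and parameter-free, with ties broken
  toward the higher rank. A constant curve returns the constant with a
  warning.
* **Segment comparisons.** Transmembrane helices differ in length, so the
  default comparison of per-segment centrality distributions is the
  unpaired Wilcoxon rank-sum test; a signed-rank variant that pairs values
  by descending rank after truncation to the smaller group is provided for
  completeness, since rank pairing is the only defensible pairing when the
  segments have no natural correspondence.
* **Sequence neighbours.** Residue pairs adjacent in sequence are excluded
  from interaction *profiling* (their backbone contacts are trivial) but
  retained as network contacts; ligand pairs are never excluded.

## Synthetic data: what it emulates, and what it does not

Every stage is exercised by generators whose ground truth is known by
construction:

* `make_scaffold()` builds a serpentine bundle of parallel segments with an
  exactly known heavy-atom contact set and a synthetic
  Ballesteros–Weinstein map (segments `TM1..TMn`, mid-segment anchors).
* `gaussian_ensemble()` draws frames as the reference plus per-residue
  rigid Gaussian displacements with a prescribed residue-residue
  correlation matrix (per axis, covariance `sigma^2 rho`; default
  `sigma = 0.05` nm keeps the contact topology stable). Frames are
  independent by default; an AR(1) mode with chosen lag-1 autocorrelation
  exists to exercise stride logic.
* `planted_path_ensemble()` raises correlations along a chosen contact
  chain using a first-order autoregressive profile `rho_chain^|a-b|` plus a
  weak constant background, completed to positive-definite by eigenvalue
  clipping (a literal constant correlation on chain neighbours is not a
  valid correlation matrix). Recovery of the chain by `optimal_path()` is
  the end-to-end test of the whole correlation-network stack.
* `interaction_fixture()` realises hydrogen-bond, hydrophobic and
  salt-bridge geometries exactly at requested distances/angles, toggling
  per frame according to a presence bit pattern.
* `multibasin_trajectory()` plants jittered conformational basins with
  controlled within-basin spread and between-basin RMSD.
* `pocket_phantom()` places non-overlapping obstacle spheres inside the MER
  so the free volume has a closed form (sphere minus sphere-sphere
  intersections).

These generators emulate the *statistical* structure the analyses assume —
prescribed correlations, contact topologies, interaction geometries,
cavity volumes — not physical chemistry: there are no force fields, no
solvent, no realistic side-chain rotamers, and displacement amplitudes are
small and Gaussian. Passing tests therefore demonstrate that the estimators
and graph algorithms recover planted structure correctly; they do not
demonstrate anything about force-field accuracy or sampling convergence of
a real simulation.

## Numerical choices and degenerate inputs

* Units are nm and ps throughout; Angstrom-based files are converted on
  load. Residue numbering follows the input topology verbatim.
* Kabsch superposition uses the SVD with a reflection guard
  (`det` correction); fitting is refused below 3 atoms.
* A frozen (repeated-frame) trajectory is rejected by the MI estimator with
  advice to jitter — repeated points make kNN distances zero.
* Pocket grid points on the MER boundary are included (distance ≤ radius);
  the grid is axis-aligned to the MER-defining frame, so absolute volumes
  carry a small grid-orientation dependence (< 1% at 0.05 nm spacing) that
  cancels in state-to-state comparisons.
* Cluster ids are ranked by size with ties broken by the earlier medoid
  frame; the medoid minimises the summed within-cluster RMSD.
* Hydrogen covalency is inferred geometrically (H within 0.13 nm of its
  nearest heavy atom); no protonation states are ever guessed, and ligand
  charge groups must be declared explicitly for salt-bridge detection.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run entirely on synthetic data at
desk scale, sizes chosen to make the statistical tolerances meaningful:
Gaussian oracles at `N = 1200` samples and 10 seeds; 50 random graphs with
up to 7–8 nodes against exhaustive path enumeration; 20 planted-path seeds
at 1200 frames; 20-frame three-basin clustering; pocket phantoms at 0.05
and 0.025 nm spacing. A typical receptor-scale analysis (300 residues,
1200 strided frames) runs in minutes on one core, dominated by the
per-pair MI estimation.

## Known limitations

* PLIP-style profiling is partial by design: no aromatic stacking,
  pi-cation, halogen bonds, water bridges or metal coordination.
* The MER is user-specified; the package tracks a known pocket's volume and
  does not discover cavities.
* Betweenness and path analyses treat the network as static over the
  analysed window; no time-resolved or community analyses.
* Reproducing published per-residue numbers for a specific receptor
  requires that study's trajectories; the shipped fixtures validate the
  mathematics, not any particular simulation.
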