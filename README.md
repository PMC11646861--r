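# allonet

Dynamic residue-interaction networks and generalized correlation analysis
for molecular dynamics (MD) trajectories, in R.

## The problem

MD simulations of G protein-coupled receptors and other allosteric proteins
produce microseconds of coordinates from which one wants mechanistic
summaries: which conformational states are visited, which residue–residue
and residue–ligand interactions persist, how the binding pocket breathes,
and — centrally — how motion in the ligand site is *communicated* to the
effector site. `allonet` implements that post-simulation pipeline for
structural bioinformaticians: conformational readouts (RMSD, RMSF,
single-linkage conformational clustering, side-chain dihedrals, minimum
distances), geometric interaction profiling with per-frame probabilities,
grid-based pocket volume inside a fixed maximum-englobing region, and
correlation-weighted dynamic networks.

## The statistic at the core

The coupling between residues *i* and *j* is measured by the generalized
correlation coefficient

> r_MI(i,j) = [1 − exp(−(2/3) I(i,j))]^(1/2) ∈ [0, 1],

where I(i,j) is the mutual information between the 3-D positions of the
two alpha carbons, estimated non-parametrically with the Kraskov
k-nearest-neighbour estimator (k = 6, frames sampled every 1 ns so they are
decorrelated):

> I = ψ(k) − ⟨ψ(n_i + 1) + ψ(n_j + 1)⟩ + ψ(N),

with ψ the digamma function and n_i, n_j marginal neighbour counts within
the k-th joint-neighbour distance (max-norm across the two 3-D blocks).
For jointly Gaussian motion with per-axis correlation ρ, r_MI = |ρ|
exactly, which is the package's built-in correctness oracle.

The dynamic network links residues whose heavy-atom contact frequency
(minimum distance < 0.45 nm) is ≥ 0.75, weights edges by r_MI, and analyses
betweenness centrality (normalized by 2/((n−1)(n−2)) for nodes,
2/(n(n−1)) for edges), eigenvector centrality of the weighted adjacency,
knee-thresholded per-helix centrality distributions (Wilcoxon comparisons),
and optimal communication paths that maximise the product of edge
correlations (minimise Σ −log w).

## Worked example

Everything below runs on synthetic data with known ground truth — a
three-segment helix bundle whose residues 2→3→4→5 were generated with a
planted chain of correlated motion (ρ = 0.9 along the chain, 0.05
background):

```r
library(allonet)

scaffold <- make_scaffold(n_segments = 3, residues_per_segment = 4)
traj <- planted_path_ensemble(scaffold, chain = c(2, 3, 4, 5),
                              rho_chain = 0.9, rho_bg = 0.05,
                              n_frames = 1200, seed = 1)

contacts <- contact_frequency(traj, distance_cutoff = 0.45)
pairs <- which(upper.tri(contacts) & contacts >= 0.75, arr.ind = TRUE)
corr <- correlation_matrix(traj, kraskov_params(k = 6, stride_ps = 1000),
                           pairs = cbind(rownames(contacts)[pairs[, 1]],
                                         colnames(contacts)[pairs[, 2]]))
net <- build_network(contacts, corr, frequency_cutoff = 0.75)
net
#> dynamic network: 12 nodes, 12 edges

bc <- betweenness_centrality(net)
head(bc$nodes[order(-bc$nodes$betweenness), ], 3)
#>   node betweenness
#> 2    2   0.4181818
#> 3    3   0.4000000
#> 7    7   0.2909091

optimal_path(net, source = "2", target = "5")
#> path: 2 -> 3 -> 4 -> 5   (length 0.4136, product of correlations 0.6613)

round(corr["2", "3"], 3)
#> [1] 0.868
```

The estimated edge correlation 0.868 recovers the planted ρ = 0.9 to
estimator accuracy, the chain interior dominates the betweenness ranking,
and the optimal path from residue 2 to residue 5 is exactly the planted
chain — the end-to-end property the whole stack is built to deliver.

For real systems, `load_system()` reads PDB/GRO topologies with
multi-model-PDB or DCD trajectories, `concatenate_tails()` pools replica
tails, `read_bw_map()` supplies Ballesteros–Weinstein helix labels (a
partial TAS2R46 anchor table ships in `inst/extdata/`), and
`interaction_probabilities()`, `pocket_volume_series()`,
`sidechain_dihedral()` etc. provide the conformational readouts. The
methods vignette (`vignettes/allosteric-network-analysis.Rmd`) documents
every model, parameter and design decision.

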