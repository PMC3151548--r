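---
title: "Methods and design of trajan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of trajan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajan)
```

`trajan` bundles a family of coarse-grained analyses of protein
structures and molecular-dynamics trajectories behind one set of
containers. This vignette is the package's account of the underlying
models, the tunable parameters and their defaults, the numerical choices
made where the methods leave room, and what the synthetic validation does
and does not demonstrate.

## Containers and conventions

Structures are atom tables in file order; the residue identity key is
`(segid, resid, insertion code)`, with the chain ID standing in when the
segment field is blank, so both PDB dialects resolve. Trajectories store
one row per frame with 3N columns, in Å. All indices in the API and in
output files are 1-based (the R convention). Atom selections use the
slash syntax `/SEGID/RESID/ATOM` with `*` wildcards, comma lists and
`@(a-b)` residue ranges (the en-dash is tolerated inside ranges). This
grammar is a minimal reconstruction of the original field tool's syntax,
which is documented only by example; anything beyond the three-field form
is an extension of this package.

DCD files are read in either byte order: the leading Fortran record
marker must decode to 84 in the file's native order, which disambiguates
endianness without user input. Files with fixed-atom lists store partial
frames and are rejected with an explicit error rather than mis-read.
Masses, which DCD and PDB files do not carry, are inferred from the
element implied by the atom name, with standard atomic weights.

## Elastic network models

The network energy is the Hookean sum `E = ½ Σ k_ij (d_ij − d⁰_ij)²` over
the spring list; equilibrium lengths `d⁰` are taken from the input
structure. Two force-constant models:

* **cutoff** (default): k = 10 for sequence-adjacent Cα pairs
  (consecutive `resid` within one segment — chain breaks do not get the
  stiff constant), k = 1 for any other pair within the distance cutoff
  (default 12 Å, user-settable).
* **kovacs**: every pair interacts with `k_ij = C (d₀/d_ij)⁶`,
  `d₀ = 3.8 Å` (the mean adjacent Cα–Cα distance, so sequence neighbours
  feel ≈ C) and `C = 40 kcal mol⁻¹ Å⁻²` by default. The inverse-sixth-
  power decay makes an explicit cutoff unnecessary.

The Hessian is assembled from the 3×3 blocks `±k uuᵀ` (`u` the unit bond
vector) and diagonalized with a dense symmetric eigensolver. Mass
weighting (`H → M^{-1/2} H M^{-1/2}`) is off by default, the classic
anisotropic-network convention. Near-zero (rigid-body) modes are
identified by `|λ| < 10⁻⁸ · λ_max`, the double-precision eigensolver
floor; a connected, non-collinear network has exactly six, and more
triggers a warning about internal disconnection or collinearity.

Derived quantities:

* **Perturbation response**: stiffening all springs that touch residue
  `i` by δk = 0.1 (the conventional magnitude) and contracting the
  perturbation Hessian with mode `m` gives
  `δω_im = Σ_springs∋i δk (û·(ν_m,j − ν_m,i))² ≥ 0`; responses can be
  written into the B-factor column of a PDB for coloring.
* **Theoretical B-factors**: `B_i = (8π²/3) kT Σ_m |ν_m,i|² / λ_m` over
  the user-chosen number of lowest internal modes, in Å² with T in K and
  spring constants in kcal mol⁻¹ Å⁻² (Boltzmann constant in kcal/mol/K).
  The 8π²/3 prefactor makes the values directly comparable to
  crystallographic B columns; the Pearson correlation against the
  experimental column is scale- and offset-invariant, so the prefactor
  convention does not affect it.
* **Involvement coefficients**: `I_m = |ν_m · Δr| / |Δr|` for the
  displacement between two conformers sharing the node set; the
  cumulative square overlap over all internal modes equals 1 whenever the
  displacement is orthogonal to the rigid-body space (eigenvector
  completeness). Values above the conventional 0.2 threshold are
  reported.
* **Mode correlations**: the pseudo-covariance `Σ_m ν_m ν_mᵀ / λ_m` over
  the chosen modes, reduced to residue level by 3×3 block traces and
  normalized to unit diagonal.

## Motion correlation

Fluctuations are taken about the trajectory mean, per atom or per residue
(mass-weighted centroids optional). No superposition is applied
implicitly; `superpose_trajectory()` provides an explicit least-squares
fit when the input is not already aligned, keeping raw and fitted
analyses distinct.

DCC is the normalized covariance of the 3-vector displacements with
population (1/F) averaging; ±1 mark perfectly parallel/anti-parallel
motion, and perpendicular correlated motions score 0. LMI is the Gaussian
mutual information `I = ½(ln det C_i + ln det C_j − ln det C_ij)` from
the 3×3 marginal and 6×6 pair covariances, which does detect
perpendicular coupling. The original tool constrains LMI output to
[0, 1] without printing its mapping; this package uses the Gaussian-
channel normalization `r = √(1 − exp(−2I/3))` (dimension 3), which is 0
at independence, 1 for identical variables, and reduces to `|ρ|` for
isotropically correlated components. The mapping is isolated in
`lmi_to_correlation()` so an alternative convention is a one-line change.
LMI needs more than 6 frames (the 6×6 covariance must be estimable) and a
singular marginal covariance — frozen atoms — is an error with a
regularization hint rather than a silent infinity.

## Protein structure networks

The interaction strength between nodes is
`I_ij = 100 · n_ij / √(N_i N_j)` percent, with `n_ij` the number of
side-chain atom pairs within the 4.5 Å default cutoff and `N` per-type
normalization factors expressing contact capacity. "Side chain" means all
atoms except backbone N, CA, C, O (and backbone hydrogens) — **glycine
therefore has no side-chain atoms and cannot form edges**. Hetero nodes
(GTP, GDP, retinal, Mg²⁺) use *all* their atoms, matching how their
normalization factors were derived from whole-molecule contact counts:
retinal 170.13, GDP 220.19, GTP 274.78, Mg²⁺ 22.01 in GTP-bound and
14.65 in GDP-bound GTPases (key `MG_GDP`). Hydrogens are excluded from
contact counts by default (switchable); the amino-acid factors are the
standard contact-capacity table and users can add or override entries.

Edges require `I_ij ≥ I_min` and skip `j = i ± n` (default n = 2) within
a chain; inter-chain pairs are always eligible, since the exclusion
models covalent adjacency. Hubs are nodes with degree ≥ 4 by default —
the inclusive reading, chosen because the field's own usage alternates
between "more than 4" and "at least 4"; a strict switch is provided. Node
clusterization is plain connected components, numbered deterministically
by smallest member. `I_critic` is the `I_min` at which the largest
cluster reaches half its `I_min = 0` size, linearly interpolated between
bracketing grid points (the conventional grid is 0–5 % in 0.5 % steps);
when the half size is not reached the result is flagged
`I_critic > max(grid)`.

Over a trajectory the package reports per-edge frame frequencies, stable
hubs (hub in more than 50 % of frames by default), and hub-correlation
pairs. The hub-correlation statistic is the *joint-hub* frame fraction
(both nodes simultaneously hubs in more than the stability fraction of
frames); a matching-state variant (indicator agreement) is available
behind a flag, but the joint definition is the default because only it
expresses synchronized hub behaviour rather than synchronized absence.

## Communication paths

Shortest paths are counted in hops — all PSN edges cost 1, so Dijkstra's
algorithm reduces to breadth-first search — and *all* tied shortest paths
are enumerated, since frame-to-frame frequency statistics are only
well-defined over the complete tie set. A strength-weighted mode (cost
`1/I_ij`) exists behind a flag as an explicit extension. The correlation
filter keeps a path when at least one internal residue has
trajectory-level motion correlation (DCC or LMI) at or above the cutoff
with either endpoint; two-node paths have no interior and are dropped
unless explicitly waived. A path's frequency is the number of frames
whose shortest-path set contains the exact node sequence (or its
reversal) divided by the total frame count, which guarantees every
reported path is a valid shortest path in at least one frame.

## Conformational clustering

Metrics: RMSD with optimal superposition by default (a Kabsch
least-squares fit), or DRMS — the root-mean-square difference of the
intra-frame pairwise distance matrices — which needs no superposition and
is exactly rotation-invariant. Algorithms:

* **leader-like**: order-dependent by construction (each frame is
  compared only with centres found so far); modalities `nearest`
  (default), `first` (first centre within threshold), and `backward`
  (scan clusters in order of most recent occupancy — fast on
  time-correlated frames, accuracy close to `nearest` on separated
  wells).
* **QT-like**: the threshold is the cluster *radius* about the centre
  frame; the largest candidate cluster is extracted repeatedly. Ties on
  candidate size are broken toward the lowest centre frame index, for
  determinism.
* **hierarchical**: average-linkage agglomeration cut at the threshold
  height (the original tool does not state its linkage; average linkage
  is this package's choice and is recorded in output headers). Centres
  are medoids; the result is frame-order independent.

Two-pass clustering runs pass 1 on a frame subset, then assigns every
frame to the nearest centre within the threshold; frames farther than the
threshold from all centres found new clusters that are immediately
available to later frames, so sparse first-pass subsets cannot silently
orphan outliers. Distance matrices can be saved — plain-text header
(metric, superposition, selection, frame count) plus binary upper
triangle — and reloading reproduces clustering bit-for-bit; a header
mismatch against the requested settings is an error, refusing silent
reuse.

## Free-energy-surface analysis

The input is a microstate label timeseries (one integer per frame, e.g.
the clustering module's assignment column). The transition network counts
directed lagged pairs `(s_t, s_{t+lag})`; weights are visit counts.
Symmetrizing the counts (detailed-balance enforcement) is available but
off by default: the profile construction is defined on sampled
transitions.

The committor `p_fold` solves `p_i = Σ_j T_ij p_j` with `p(folded) = 1`,
`p(unfolded) = 0`; mean first passage times solve `m = 1 + T m` with
`m(target) = 0`, in units of lag steps, with unreachable states flagged
infinite. Both are exact linear solves, with harmonicity residuals at the
10⁻¹⁰ level.

The cut-based profile ranks microstates by kinetic proximity to the
reference (descending committor or ascending mfpt; ties broken by
statistical weight then state id, cuts placed between consecutive ranked
states). Each cut after the k-th state reports
`x = Z_A/Z` (cumulative weight fraction) and `ΔG = −ln(Z_AB/Z_tot)` in kT
units, with `Z_AB` the transition count crossing the cut in both
directions — so the additive constant is fixed by the total sampled
flux and profiles are comparable across runs. An interior cut with zero
crossing flux is flagged disconnected. On the symmetric two-well chains
used for validation the profile maximum falls at the cut separating the
wells (x ≈ 0.5) and the minimal-flux cut reproduces exhaustive
enumeration over all bipartitions.

Commitment probabilities `p_commit(i→j)` are measured from *every*
occurrence of `i` (sliding, overlapping starts): the fraction of starts
from which `j` is visited within τ_commit frames. Kinetic grouping forms
basins on the `n_heavy` most populated microstates (default 500) by the
≥ 0.5 rule closed transitively; the relation's asymmetry is resolved as
`max(p_ij, p_ji) ≥ 0.5` by default, with a flag to require both
directions. Remaining states are assigned to the basin with the largest
commitment ≥ 0.5 (measured as the maximum commitment to any basin
member), else left unassigned. The single-basin mode groups all states
committing to a chosen representative with p ≥ 0.5. First-passage-time
distributions guide the choice of τ_commit: starts are every visit to a
`from` state (default the target itself, i.e. return times), making a
deterministic period-k cycle a single spike at k and separating intra-
from inter-basin relaxation on multi-well chains; τ_commit should sit
inside that gap.

## Synthetic validation fixtures

The seeded generators define the study conditions used throughout the
test suite and acceptance script:

* `gen_toy_structure()` — a chemically naive but format-valid chain
  (backbone N/CA/C/O plus one CB pseudo-side-chain per residue, ±0.05 Å
  jitter). The helix geometry (100° turn, 0.9 Å rise, 3.8 Å Cα spacing,
  CB pointed at the axis) yields side-chain contacts exactly at i±3/i±4 —
  inside the 4.5 Å cutoff but outside the n = 2 exclusion — so network
  edge sets are hand-countable; the zig-zag geometry yields only
  excluded-neighbour contacts. Every contact is bookkept in a ground-
  truth record.
* `gen_gaussian_traj()` — frames from a multivariate normal with a
  prescribed 3N×3N covariance about the structure's coordinates, with the
  analytic DCC as ground truth. Problem sizes used in the tests (10–30
  nodes, 2000–10⁴ frames) keep the whole suite under half a minute.
* `gen_markov_traj()` — block-structured Markov chains (two wells of 5
  states at intra/inter rates 0.1 / 2·10⁻⁴ over 2·10⁵ steps, and three
  wells of 4 states at 0.1 / 10⁻⁴ over 4·10⁵ steps), chosen so the
  intra-well relaxation (~10 steps) and inter-well passage (~10³–10⁴
  steps) are separated by two orders of magnitude, with τ_commit = 100
  inside the gap — the regime the kinetic-grouping method targets.

What passing these tests shows: the implementations agree with
independent naive oracles, closed forms, and Monte-Carlo simulation on
inputs where truth is computable. What they do not show: behaviour on
real proteins — the toy peptides have no physical force field, a single
side-chain atom per residue, and isotropic Gaussian fluctuations without
the anharmonicity, solvent memory, or alignment noise of real
trajectories; and the Markov fixtures are exactly Markovian at lag 1,
which MD microstate series are not. Parameter defaults (4.5 Å contacts,
n = 2 exclusion, hub degree 4, stability 0.5, δk = 0.1, I threshold 0.2)
follow the field's conventions and are all user-settable.

## Known limitations

* The LMI [0, 1] mapping is this package's declared convention; absolute
  LMI values are comparable within `trajan` runs but not necessarily with
  other implementations (rank orderings are).
* Hierarchical clustering materializes the full F×F distance matrix;
  beyond ~10⁴ frames use two-pass or leader clustering.
* mfpt values are finite for any state that *can* reach the target, even
  when absorption elsewhere is possible; with reducible chains interpret
  them together with the reachability flags.
* The cut-based profile is the ranking approximation to the minimum-cut
  construction; exhaustive-cut agreement is verified only on small
  networks.
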