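---
title: "Methods: contact-score state calling, equivariant scoring and multi-conformation efficacy classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models and procedures `dyneff` implements, the
parameters that matter, the synthetic study conditions, and the numerical
and design choices made where the design was genuinely open.

## 1. Contact-score activation calling

Class A GPCR activation rearranges a small set of TM3–TM7 contacts. The
residue–residue contact score between residues $a$ and $b$ is

$$\mathrm{RRCS}(a,b) \;=\; \sum_{i \in a}\sum_{j \in b} k(d_{ij}),\qquad
k(d)=\begin{cases}1 & d \le d_\mathrm{full}\\
\frac{d_\mathrm{zero}-d}{d_\mathrm{zero}-d_\mathrm{full}} &
d_\mathrm{full} < d < d_\mathrm{zero}\\
0 & d \ge d_\mathrm{zero}\end{cases}$$

over **heavy atoms only** (hydrogens are parsed but flagged out). The
kernel constants default to the published RRCS values
$d_\mathrm{full}=3.23$ Å and $d_\mathrm{zero}=4.63$ Å and are exposed in
`rrcs_kernel()`.

Per-frame scores are **normalized as a ratio** to the same pair's score in
an initial activated reference conformation. We read "normalized" as a
ratio rather than a difference because the downstream decision rule —
above 1 favors active, below 1 favors inactive — only has meaning on a
ratio scale; a difference mode is available via `delta_rrcs(mode =
"difference")` for exploration, but `call_state()`'s threshold semantics
assume the ratio. Pairs whose reference score is below
$\varepsilon = 10^{-9}$ are flagged undefined instead of divided.

The four default switch pairs are 3x43–7x49, 3x43–7x53, 3x46–7x53 and
3x50–7x53 (`default_switch_pairs()`). The frame-level call aggregates the
per-pair calls by **majority over defined pairs, with an exact tie mapped
to "intermediate"**; this aggregation rule is the package's own choice —
any fixed aggregation would do, and majority is the least committal.
Frames whose pairs are all undefined are called "undefined" with a
warning.

Frame filtering (`filter_frames()`) applies three stages in a fixed
order: a backbone-RMSD convergence filter (drop a frame when it deviates
from the trailing-window median by more than `mad_mult` window-MADs;
window 10, multiplier 5 by default), deduplication of profiles equal
after rounding to 3 decimals (lowest frame id wins), and an optional
user-supplied pocket-consistency hook — no pocket-volume algorithm is
built in because none is canonical at this scale.

Representative selection (`select_representatives()`) deduplicates, then
runs greedy farthest-point sampling in normalized-profile space,
stratified so active- and inactive-called frames are represented
proportionally. Determinism: the seed frame is the lowest frame id of each
stratum and distance ties break to the lower frame id. Whether published
"nonredundant" selections used clustering or profile uniqueness is not
derivable from their counts; farthest-point sampling is one admissible,
fully deterministic reading, and the counts themselves are not
reproduction targets.

## 2. Alignment and PCA

`kabsch_align()` computes the least-squares proper rotation via SVD of the
cross-covariance with the usual determinant sign correction, so
reflections are never returned; inputs with fewer than 3 points or
collinear geometry are rejected. `run_pca()` is `stats::prcomp` on the
mean-centered $n \times 3N$ Cα matrix, covariance divisor $n-1$, EVR =
eigenvalue / total variance. Component signs are fixed by making each
component's largest-magnitude loading positive so projections are
deterministic. PCA is run **per state**, after per-state alignment;
published EVR values depend on their MD trajectories and are not targets
here.

## 3. Complex graphs

`build_complex_graph()` assembles three node kinds: pocket protein nodes,
ligand atoms, and one virtual node per aromatic ring at the unweighted
centroid of its members (rings found by a smallest-set-of-smallest-rings
search restricted to aromatic-flagged atoms). Geometric edges use closed
cutoffs — 4.5 Å atom–atom for pairs involving a ligand or virtual node,
8.0 Å Cα–Cα for protein–protein adjacency — with distances binned on a
0.5 Å grid. These are conventional contact-graph values, configurable in
`geometric_cutoffs()`. A $10^{-9}$ Å offset is added before the bin floor
so that a distance sitting exactly on a bin boundary cannot flip bins
under floating-point jitter (e.g. after a rigid translation).

Structural edges carry covalent bonds, virtual-node ring membership, and
noncovalent interactions from a deliberately minimal detector
(`detect_interactions()`): H-bond at donor–acceptor ≤ 3.5 Å with
D–H···A ≥ 120° when hydrogen positions are present (distance-only
otherwise), π–π at centroid distance ≤ 5.5 Å, cation–π ≤ 6.0 Å, salt
bridge ≤ 4.0 Å. An external interaction table overrides it. Ligands are
supplied as explicit atom/bond/aromaticity tables so the core needs no
chemistry toolkit; SMILES perception is out of scope by design.

## 4. The equivariant scorer

Each block applies, in order: neighborhood-masked multi-head
self-attention (4 heads, self-loops included, additive per-head edge bias
on the logits), an edge update projecting the per-edge attention vector
into edge-feature space through two projections with a residual, then the
message / coordinate / aggregation / node-update equations

$$m_{ij}=\varphi_e(h_i,h_j,\lVert x_i-x_j\rVert,a_{ij}),\quad
x_i' = x_i + \sum_{j\ne i}(x_i-x_j)\,\varphi_x(m_{ij}),\quad
m_i=\sum_{j\in N(i)} m_{ij},\quad h_i'=\varphi_h(h_i,m_i).$$

$\varphi_e$ and $\varphi_h$ are two-layer ReLU MLPs ($\varphi_h$
residual), $\varphi_x$ is a scalar tanh gate scaled by `coord_scale`
(default 0.1) to bound per-edge coordinate steps. Coordinates enter only
through distances and differences, which gives E(3) equivariance by
construction; the suite verifies invariance of score and penultimate
features and correct transformation of coordinates under random
isometries at $10^{-5}$ tolerance (double precision internally; the
tolerance leaves headroom for single-precision ports).

Desk-scale defaults: embedding width $D=64$, edge width $E=16$, $T=3$
blocks, mean pooling over ligand + virtual nodes, a 32-unit hidden head.
The penultimate feature is the pooled pre-head vector, so its dimension
is $D$; the "true" dimension of larger pretrained scorers is not fixed
here, and all downstream code is dimension-agnostic.

Gradients are exact reverse-mode derivatives from a small in-package tape
(`R/tape.R`) covering the matrix ops, gathers/scatters and group softmax
the network needs; a finite-difference check on a toy complex holds at
$10^{-4}$ relative error. No pretrained weights are shipped: "transfer
learning" is realized by pretraining the trunk on a synthetic task,
freezing it, and extracting penultimate features (head-only training is
the default; nothing prevents unfreezing, but the frozen-feature route is
what the multi-conformation head consumes).

## 5. Efficacy classification and evaluation

Labels: agonist iff $E_\mathrm{max} > 50\%$ (strict; 50 % is a
nonagonist). The head is a 64–32–1 ReLU/ReLU/sigmoid MLP trained with
binary cross-entropy and Adam, batch 32, 25 epochs, 5 seeded repetitions
(seeds `base_seed + 0..4`). The learning rate is not pinned by the
training protocol we follow; we default to $10^{-2}$, at which the head
reliably converges within 25 epochs at desk scale. Inputs are
standardized per feature with training-set statistics. Per-ligand
features are the penultimate vectors of the selected conformations
concatenated **in the recorded conformation order**.

Baselines follow fixed sign conventions: for active-state docking a lower
(better) score ranks more agonist-like, and the two-states difference
$\Delta = s_\mathrm{active} - s_\mathrm{inactive}$ ranks more agonist-like
when more negative. These orientations are the package's choice (flippable
via `orientation =`); published work does not state the sign. The RF
baseline is `randomForest` on the full per-ligand score vector with
out-of-fold predictions.

AUC is computed by midrank Mann–Whitney — exactly the TPR–FPR integral in
the continuous case, with exact tie handling — and cross-checked in tests
against an $O(n^2)$ pair-count oracle. MCC with a zero denominator is
defined as 0. Scaffold splits cluster ECFP4-type fingerprints by single
linkage at Tanimoto ≥ 0.4 (threshold configurable), assign clusters whole
to folds largest-first into the smallest fold, and never split a cluster.
The per-state score test is Welch's unequal-variance two-sided $t$-test;
the underlying publication does not name its test and Welch's is the
conservative default for unequal spreads. Reported evaluations use pooled
out-of-fold predictions under three-fold CV (per-fold metrics are also
returned), because pooling scores every ligand exactly once and avoids
the high variance and slight pessimistic bias of a single small holdout.

## 6. Synthetic study conditions

The generators encode the study conditions once, as defaults, and tests
run against them:

* `gen_two_state_ensemble()` — 200 frames per state by default. Each
  residue is a Cα plus one side-chain proxy heavy atom. Switch-pair side
  chains sit at 3.3 Å in the active geometry and `displacement` (default
  1.5 Å) further apart in the inactive one, pushing them past the kernel
  zero at 4.63 Å. The noiseless reference frame uses 3.8 Å — an
  "initial activated" structure looser than the relaxed active ensemble,
  as a starting structure typically is — so active frames normalize above
  1 and inactive frames near 0. Gaussian coordinate noise (default
  0.1 Å, a tight-ensemble scale) perturbs every atom. The pair graph is
  embedded by BFS at unit scale and scaled per state, which requires the
  pair graph to be acyclic (the canonical switch set is a tree).
* `gen_score_table()` — Normal scores per (class, state) with the
  published per-ligand moments as defaults: agonist −6.53 ± 0.55
  (active) / −6.02 ± 0.66 (inactive); nonagonist −4.95 ± 0.55 (active) /
  −5.36 ± 0.79 (inactive), kcal/mol, 200 conformations per state. The
  Normal family is the minimal assumption consistent with the box
  distributions shown for these ligands.
* `gen_feature_ensemble()` — standard-normal features, class signal
  $\delta$ (in feature-SD units) along one random direction. In
  `state-contrast` mode agonists are shifted $+\delta/2$ in active blocks
  and $-\delta/2$ in inactive blocks while nonagonists are unshifted, so
  a single conformation block carries weak signal and the cross-state
  contrast carries most of it — the structure the multi-conformation
  claim is about. Defaults: 120 ligands, 6 conformations, $P=16$.
* `gen_fingerprints()` — sparse random cluster cores (512 bits, density
  0.15) with 2 % member bit flips, yielding within-cluster Tanimoto well
  above and between-cluster well below the 0.4 split threshold.

What the generators do **not** emulate: real protein geometry and
energetics, docking-pose physics, heavy-tailed or multimodal score
distributions, scaffold-activity cliffs, class imbalance, and label
noise. Passing tests therefore demonstrate correctness of the machinery
and the qualitative orderings under clean conditions, not performance on
experimental data.

## 7. Numerical conventions and degenerate inputs

* Coordinates in Å throughout; PDB I/O uses the wwPDB fixed-column
  dialect at 3 decimals, and the round-trip is exact at that precision.
  Alternate locations keep the highest occupancy (first on ties, logged).
* The contact kernel sums its per-pair values in sorted order, making
  `residue_contact_score(a, b)` bitwise-equal to its argument swap.
* Kabsch requires ≥ 3 non-collinear points; PCA requires ≥ 2 frames and
  caps components at $\min(n-1, 3N)$.
* Empty pockets, missing Cα atoms, ragged feature lengths, dangling graph
  references, single-class training sets and out-of-range selections all
  raise informative errors; missing Emax or scores exclude the record
  with a log message rather than silently imputing.
* All stochastic steps take explicit seeds; repetition seeds are derived
  as documented offsets from a base seed.

## 8. Pipeline sizes

`run_pipeline()`'s defaults (60 frames per state, 120 ligands, 16-d
features, 5 repetitions) are chosen so a full synthetic run completes in
seconds on one core while every stage still exercises its real code path;
all sizes scale up through the config. The acceptance script uses 200
conformations per state for the score-distribution test — matching the
ensemble-docking snapshot count — and 10 seeds for the classifier
summaries.

## 9. Known limitations

* The built-in interaction detector is intentionally minimal; for real
  complexes, supply interactions from a dedicated IFP tool.
* The scorer is desk-scale and CPU-bound; it demonstrates the
  architecture and its invariances, not large-scale pretraining.
* Only binary efficacy is modeled; partial and inverse agonism are out of
  scope, as is probability calibration.
* mmCIF and binary trajectory formats are not read; convert to
  multi-model PDB upstream.
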