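# dyneff

Conformational-ensemble graph learning for GPCR ligand efficacy.

## The problem

G protein–coupled receptors (GPCRs) interconvert between active and
inactive conformations, and whether a ligand behaves as an **agonist**
(maximal response E<sub>max</sub> > 50 %) or a **nonagonist**
(E<sub>max</sub> ≤ 50 %) is encoded less in any single crystal structure
than in how the ligand engages the receptor's conformational equilibrium.
`dyneff` is aimed at computational chemists and structural bioinformaticians
who want to classify ligand efficacy from multi-conformation receptor
ensembles rather than from one static snapshot.

The package implements the full desk-scale workflow:

1. **Activation-state calling by contact scoring.** For residue pairs *a*,
   *b* (addressed by Ballesteros–Weinstein numbers; default switch set
   3x43–7x49, 3x43–7x53, 3x46–7x53, 3x50–7x53), the residue–residue
   contact score sums a piecewise-linear heavy-atom kernel over all cross
   atom pairs:

   RRCS(a,b) = Σ<sub>i∈a, j∈b</sub> k(d<sub>ij</sub>), with k(d) = 1 for
   d ≤ 3.23 Å, 0 for d ≥ 4.63 Å, linear in between.

   Per-frame scores are normalized as a ratio to an initial activated
   reference conformation; a normalized value above 1 favors the active
   state, below 1 the inactive state, and the per-frame call is the
   majority over the switch pairs. The profile also drives redundancy
   filtering and greedy farthest-point selection of representative
   conformations.
2. **Ensemble geometry.** Kabsch superposition on Cα atoms, PCA of the
   *n* × 3*N* flattened Cα coordinate matrix with explained-variance
   ratios, and TM5/TM6-style Cα–Cα distance maps.
3. **Complex graphs and an equivariant scorer.** Heterogeneous graphs
   G = (V, E<sub>geometric</sub>, E<sub>structural</sub>) with protein,
   ligand-atom and virtual aromatic-centroid nodes feed an E(3)-equivariant
   message-passing network:

   m<sub>ij</sub> = φ<sub>e</sub>(h<sub>i</sub>, h<sub>j</sub>,
   ‖x<sub>i</sub> − x<sub>j</sub>‖, a<sub>ij</sub>);
   x<sub>i</sub>′ = x<sub>i</sub> + Σ<sub>j≠i</sub>(x<sub>i</sub> −
   x<sub>j</sub>) φ<sub>x</sub>(m<sub>ij</sub>);
   m<sub>i</sub> = Σ<sub>j∈N(i)</sub> m<sub>ij</sub>;
   h<sub>i</sub>′ = φ<sub>h</sub>(h<sub>i</sub>, m<sub>i</sub>),

   preceded by neighborhood-masked multi-head attention with an additive
   edge bias, and with edge features updated from projected attention
   values. The pooled pre-head representation (the *penultimate feature*)
   is extracted per complex.
4. **Transfer-learning efficacy head and baselines.** Penultimate features
   of a ligand across the selected conformations are concatenated and fed
   to a 64–32–1 ReLU/sigmoid MLP (binary cross-entropy, Adam, batch 32,
   25 epochs, 5 seeded repetitions). Baselines: single-conformation score
   ranking, active-minus-inactive two-states differences, and a random
   forest on the full ensemble score vector. Evaluation uses AUC (midrank
   Mann–Whitney), accuracy, MCC, precision and recall under random or
   Tanimoto-clustered (ECFP4-style) scaffold splits, plus a per-state
   Welch test of docking-score distributions.
5. **Synthetic study conditions.** Seeded generators emulate everything the
   physical pipeline would obtain from MD, docking and scoring: two-state
   ensembles with switchable contact geometry, per-state Normal docking
   scores with agonist/nonagonist patterning, multi-conformation feature
   ensembles with a tunable (optionally state-contrasted) class signal,
   and clustered fingerprints — so the whole workflow runs offline.

## Worked example

```r
library(dyneff)

# two-state receptor ensemble (100 frames per state) and its contact profile
sim     <- gen_two_state_ensemble(n_frames = 100, noise_sd = 0.1, seed = 1)
ens     <- bind_ensembles(sim$active, sim$inactive)
profile <- delta_rrcs(ens, sim$bw_map, pairs = sim$pairs,
                      reference = sim$reference)
calls   <- call_state(profile)
table(calls$frame_call, sim$truth$state)
#>            active inactive
#>   active      100        0
#>   inactive      0      100

sel <- select_representatives(profile, calls, n_target = 40)
length(sel)
#> [1] 40

# multi-conformation features with a state-contrasted class signal,
# evaluated by the transfer-learning head under 3-fold CV, 5 repetitions
fe     <- gen_feature_ensemble(delta = 2, mode = "state-contrast", seed = 2)
X      <- stack_features(fe)
plan   <- make_split(nrow(X), "random", k = 3, seed = 3)
report <- evaluate_tl(X, fe$labels, plan, n_rep = 5, base_seed = 10)
report
#> <metrics_report> 5 repetition(s)
#>   acc       0.697 +/- 0.042
#>   auc       0.769 +/- 0.035
#>   mcc       0.394 +/- 0.084
#>   precision 0.708 +/- 0.049
#>   recall    0.673 +/- 0.045

# per-state docking-score separation of an agonist-patterned ligand
st <- gen_score_table(n_ligands_per_class = 1,
                      n_conformations_per_state = 200, seed = 4)
d  <- subset(st$scores, ligand_id == st$ligands$ligand_id[1])
welch_test(d$score[d$state == "active"], d$score[d$state == "inactive"])
#> # A tibble: 1 × 5
#>       t    df  p_value mean_a mean_b
#>   <dbl> <dbl>    <dbl>  <dbl>  <dbl>
#> 1 -7.92  386. 2.54e-14  -6.52  -6.06
```

Reading it: every frame's activation state is recovered from its contact
profile; 40 non-redundant representatives are picked across both states;
the multi-conformation classifier separates agonists from nonagonists well
above chance on held-out folds; and the agonist-patterned ligand scores
significantly better (more negative) against active-state conformations.

`run_pipeline(default_run_config(seed = 1), "out/")` executes all stages in
one call and writes per-stage CSV/JSON outputs with a manifest. A thin CLI
wrapper lives at `inst/cli/dyneff.R` (`run`, `simulate`, `validate`
subcommands).

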