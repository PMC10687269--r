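# metabind

Protein-specific meta-learning for drug–target interaction (DTI) prediction
in R.

## The problem

Conventional DTI classifiers concatenate a protein representation and a
molecule representation, fit a dense head on known pairs, and then
underperform badly on *unseen* proteins and molecules: much of their apparent
skill is annotation structure (which molecules were assayed against which
targets), not binding chemistry. `metabind` attacks this in three ways:

1. **One task per protein.** Predicting the binding partners of one protein
   is treated as a learning task. A base model is meta-trained across many
   protein tasks (MAML++-style: inner-loop adaptation with learnable
   per-layer per-step rates, multi-step query losses over the adaptation
   trajectory including the unadapted parameters, task-adaptive
   self-attention over task batches), so that its initialization already
   ranks molecules for a new protein (zero-shot) and ten labelled pairs
   suffice to specialize it (few-shot).
2. **Pockets, not proteins.** Molecules bind pockets. A weakly supervised
   subgraph information bottleneck (SIB) softly assigns residues of the
   contact graph to a pocket subgraph `Z` (an n×2 row-stochastic matrix),
   trained only from global binding labels via
   `L = L_cls + λ1 L_conn + λ2 L_MI`: the classification loss on the pocket
   embedding `(Z^T H)[0, ]`, a connectivity loss
   `MSE(diag(Norm(Z^T A Z)) − diag(I2))` pushing `Z` toward hard, internally
   connected parts, and a Donsker–Varadhan mutual-information bound (a
   learned critic, gradient-ascended inside each forward pass) compressing
   away whole-protein information.
3. **Network negatives.** Nonbinding pairs are scarce, so protein–molecule
   pairs at hop distance ≥ 7 on the bipartite interaction network are
   sampled as negatives, relieving the per-protein annotation imbalance.

Inputs are standard: PDB structures (C-alpha contact graphs at a strict
8 Å cutoff), per-residue embedding matrices (e.g. from a protein language
model), SMILES (OGB-style categorical atom/bond features via Open Babel),
and delimited interaction tables with affinities in nM (< 1000 nM binding,
> 1e6 nM nonbinding, in between excluded) or explicit labels. Benchmark
splits follow sequence-cluster × molecule-scaffold logic with transductive /
semi-inductive / inductive test regimes and 5+5 few-shot sets.

Everything learnable — GCN encoders, the SIB module, the critic, the MAML++
loops with analytic backpropagation — is implemented in plain R matrix
algebra and verified against finite differences and brute-force oracles in
the test suite.

## Worked example

A fully synthetic benchmark with planted pockets makes the whole pipeline
runnable without downloads:

```r
library(metabind)

bench <- make_benchmark(synthetic_spec(seed = 5))
bench
#> <synthetic_benchmark: 64 proteins, 400 molecules, 2543 records (0.27 positive)>

splits <- make_splits(bench$records, bench$truth$family_of,
                      bench$truth$scaffold_of,
                      train_scaffold_ratio = 0.6, seed = 5)
splits
#> <split_bundle: train 839 | transductive 44 | semi-inductive 1247 | inductive 413 records>

study <- run_synthetic_study(seed = 5)   # benchmark + splits + meta-training
study$evaluation$per_protein             # zero-shot AUROC per held-out
                                         # inductive protein (unseen cluster
                                         # AND unseen scaffolds)
```

`run_synthetic_study` takes a couple of minutes. For scale: the seed-1 run of
the acceptance script (below) prints a mean zero-shot inductive AUROC of
0.464 over 8 proteins, a few-shot AUROC gain of +0.024 with 60% of 20
proteins improved by 5+5 fine-tuning, and mean pocket Jaccard 0.127 against a
random baseline of 0.084. These numbers vary substantially seed to seed — see
the vignette's discussion of desk-scale variance.

Scoring and adaptation for a single protein:

```r
model <- study$model
pred <- predict_zero_shot(model, bench$proteins$P002,
                          bench$molecules[1:5])    # tibble of scores
Z <- attr(pred, "Z")[[1]]                          # soft pocket assignment
pocket <- extract_pocket(Z, protein_id = "P002")   # residues with Z[,1] >= 0.5
jaccard(pocket, bench$truth$pockets$P002)

ten <- bench$records[bench$records$protein_id == "P002", ][1:10, ]
ft <- fine_tune(model, bench$proteins$P002,
                bench$molecules[ten$molecule_id],
                labels = as.numeric(ten$label == "binding"),
                steps = 20, lr = 0.01)             # protein-specific model
```

Real data enter through `read_structure()` (PDB text), `build_protein_graph()`
(coordinates + an embedding matrix), `build_molecule_graph()` (SMILES),
`read_interactions()` / `label_from_affinity()`, `build_network()` +
`sample_network_negatives()`, and `cluster_proteins()` / `scaffold_key()` +
`make_splits()`. A thin command-line wrapper lives at
`inst/cli/metabind.R` (`meta-train` and `predict` subcommands over JSON graph
bundles and TSV interaction tables).

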