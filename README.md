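# ppisite

Residue-level prediction of protein–protein interaction sites (PPIS)
from 3D structure, for structural bioinformaticians who want a
self-contained, inspectable implementation of a dual-view residue-graph
neural network with a structure-aware training objective — trainable
and testable on a single CPU without external databases.

## The model

A protein chain is an undirected graph `G(X, E, A)`: nodes are residues
at their side-chain centroids with 62-d feature vectors
(PSSM | HMM | DSSP | atomic | position; or 1024-d language-model
embeddings), edges connect residues whose centroids are closer than
14 Å (self-loops included), and each edge carries normalised distance
and capped sequence separation.

Two channels read the graph from a shared input projection:

* a **subgraph channel** — learnable top-k pooling with sigmoid gating,
  then propagation layers
  `H⁽ˡ⁺¹⁾ = σ(((1−α) P H⁽ˡ⁾ + α H⁽⁰⁾)((1−βₗ)I + βₗW⁽ˡ⁾))` with
  `P = D^{−1/2} A D^{−1/2}` on the pooled graph, scattered back to all
  residues;
* an **attention channel** — edge-aware multi-head graph attention
  (edge features enter the logits) followed by an
  initial-residual/identity-mapping combination
  `H⁽ˡ⁺¹⁾ = σ((1−βₗ)((1−α)H_in + αH⁽⁰⁾) + βₗ(H_in ‖ H⁽⁰⁾)W⁽ˡ⁾)`,

with `βₗ = log(λ/l + 1)`. Scaled dot-product attention fuses the views
(`softmax(H_sub H_subᵀ/√d_sub) H_AGAT`), and a three-layer MLP emits
per-residue class probabilities.

Training minimises the structured objective

```
L_total = L_correctness + λ_sol · (0.5 · L_edge + 0.5 · L_singular)
```

where `L_correctness` is cross-entropy and the structural terms are
summed MSEs between multi-scale 1-D convolutional responses of the
predicted probability signal and the true label signal — zero-sum
kernel families tuned to boundary ("01"/"10") and isolated-site
("010"/"101") patterns along the chain (`λ_sol = 0.2` by default).
All gradients come from a small built-in reverse-mode autodiff engine;
no deep-learning framework is required.

The evaluation harness reports ACC, Precision, Recall, F1, MCC, AUROC,
AUPRC and the four structural-pattern accuracies (overlapping windows
of the true label string, hit iff the prediction reproduces the window
exactly, micro-pooled over proteins). A synthetic generator produces
protein-like residue graphs with planted interaction segments at a
controllable signal-to-noise ratio, so everything above is exercised
end to end at desk scale.

## Worked example

```r
library(ppisite)

spec <- synthetic_spec(n_proteins = 20, seed = 1)  # 20 proteins, snr 5
ds <- generate_dataset(spec)                       # 14 train / 3 val / 3 test

fit <- ppis_fit(ds$train, ds$val, epochs = 20, seed = 1)
summary(fit)
#> ppis_fit: d_node 62, d_hidden 64, 2 subgraph + 4 attention layers
#>   trained 15 epochs (best epoch 5), lambda_sol 0.2
#>   final train loss 0.0007 (correctness 0.0007, edge 0.0001, singular 0.0002)
#>   best validation MCC 1.000 at epoch 5

report <- evaluate_model(fit, ds$test)
report$MCC                 # 1 on this easy high-snr fixture
report$patterns[["01"]]
#> pattern '01': 7/7 hit (accuracy 1.000)

g <- ds$test[[1]]
print(g)
#> residue_graph 'synth018': 107 residues, 3639 directed edges (cutoff 14 A),
#>   62 node features, 7 interacting
round(head(predict(fit, g)), 3)   # per-residue interaction probabilities
#> [1] 0.003 0.003 0.004 0.006 0.004 0.004
```

The training history (`fit$history`), checkpoints
(`save_checkpoint()` / `load_checkpoint()`) and graph containers
(`save_graph()` / `load_graph()`) are all plain JSON and round-trip
bit-for-bit. Real structures enter through
`read_pdb_centroids(pdb, chain)` plus a precomputed feature table
(`read_feature_table()`); see `?residue_graph`.

A thin command-line wrapper with `build-graph`, `simulate`, `train`,
`predict`, `evaluate` and `ablate` subcommands lives at
`inst/cli/ppisite.R`.

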