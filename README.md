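# potentialbind

Protein–ligand binding affinity prediction from structure, modelled as a
machine-learned interatomic potential: the network assigns an energy to
every heavy atom, and the predicted affinity is the summed energy
difference between the unbound components and the bound complex,

```
ŷ = (Σ_protein e_i + Σ_ligand e_i) − Σ_complex e_i        [pK units]
```

with each per-atom energy `e_i` produced by a shared SE(3)-invariant,
frame-averaged message-passing encoder applied to three 5 Å radius graphs
built from the same bound-pose coordinates (complex, protein, ligand).
Because atoms far from the interface have identical bound and unbound
environments, their energies cancel and the prediction — and its exported
per-atom contribution map — concentrates on the binding site.

The package is aimed at structure-based drug-discovery work: scoring posed
or predicted complexes, ranking ligand series, and inspecting which atoms a
prediction relies on. It needs only atomic numbers and coordinates (PDB +
SDF/MOL2); no charges, protonation or bond perception.

Main components:

* `parse_complex()`, `crop_pocket()`, `build_graphs()` — structure input,
  50-residue pocket cropping, radius-graph construction.
* `compute_frames()`, `apply_frame()`, `frame_average()` — signed-PCA
  frames; 4 proper rotations for SE(3) invariance (chirality-aware),
  8 for the E(3) ablation.
* `encode()`, `atom_energies()`, `predict_affinity()` — the encoder
  (128-dim embeddings, RBF × direction edge features, 4 residual
  message-passing layers) and the unbound-minus-bound prediction head.
* `balanced_mse()`, `approx_ndcg()`, `rank_loss()`, `total_loss()` — a
  label-imbalance-aware regression loss with learnable noise variance plus
  an exponentially amplified differentiable NDCG ranking loss.
* `train_affinity()`, `evaluate_affinity()`, `run_seeds()` — AdamW with
  per-batch linear warm-up and cosine annealing, seeded and reproducible;
  compiled single-precision kernels train ~500 pocket-scale complexes in
  minutes on one CPU core.
* `synthetic_spec()`, `make_dataset()`, `oracle_affinity()` — a synthetic
  complex generator with an additive pairwise oracle potential, so the
  whole pipeline is testable end to end without downloads.
* `contribution_map()`, `write_annotated_pdb()` — per-atom contributions
  as a table and as a PDB with contributions in the B-factor column for
  viewer-based inspection.

A command-line interface is installed as `exec/potentialbind` with
`prep`, `synth`, `train`, `eval` and `explain` subcommands.

## Worked example

Train on oracle-labelled synthetic complexes and inspect a prediction:

```r
library(potentialbind)

spec <- synthetic_spec(n_complexes = 625, seed = 11)
ds   <- make_dataset(spec, split = c(500, 50, 75))

cfg <- train_config(epochs = 18, seed = 1, lr_peak = 0.005)
fit <- train_affinity(ds$train, ds$val, cfg)
evaluate_affinity(fit$model, ds$test)
#> <eval_report> n=75  RMSE=1.1423  Pearson=0.9420
```

The report says the recovered model explains the held-out oracle labels
with Pearson r = 0.942 at an RMSE of 1.14 pK (label sd ≈ 2.3, label noise
0.3 pK). Per-atom attribution for one complex:

```r
st <- crop_pocket(generate_complex(spec, 601))
g  <- build_graphs(st)
pr <- predict_affinity(fit$model, g$complex, g$protein, g$ligand)
pr
#> <affinity_prediction> affinity = 5.7153 pK over 4 frames (32 atoms)

map <- contribution_map(pr, st)
write_annotated_pdb(map, st, "complex601_contrib.pdb")
```

`map` lists each atom's frame-averaged unbound-minus-bound energy; the
values sum exactly to the scalar affinity, and the annotated PDB colours
them through the B-factor column in any molecular viewer.

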