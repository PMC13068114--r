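---
title: "potentialbind: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{potentialbind: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`potentialbind` predicts protein–ligand binding affinity on the pK scale
(−log of a dissociation or inhibition constant; higher means stronger
binding) by treating the network as a machine-learned interatomic
potential. The total energy of an atomic system is modelled as a sum of
per-atom contributions, and the binding affinity is regressed on the energy
difference between the unbound components and the bound complex:

\[
\hat y \;=\; \Big(\sum_{i \in \mathrm{protein}} e_i + \sum_{i \in
\mathrm{ligand}} e_i\Big) \;-\; \sum_{i \in \mathrm{complex}} e_i ,
\]

where each \(e_i\) is produced by a shared encoder applied independently to
three radius graphs built from the same bound-pose coordinates: the complex,
the protein alone, and the ligand alone. Atoms far from the interface have
identical environments in the bound and unbound graphs, so their energies
cancel; the prediction is automatically concentrated on interface atoms,
which is also what makes the per-atom difference map
(`contribution_map()`) a meaningful interpretability output. The unbound
state reuses the bound-pose coordinates — no conformer regeneration is
attempted, so conformational relaxation energy is deliberately outside the
model.

### Input processing

A complex is parsed from a protein PDB file and a ligand SDF or MOL2 file
(`parse_complex()`). Waters are discarded, hydrogens are stripped (all
heavy atoms are kept), and alternate-location records resolve to the
highest-occupancy conformer. Metal ions and cofactors are retained as
single-atom residues; they do not count against the pocket cap, on the view
that the cap is meant to bound the amount of protein context, not to evict
small cofactors sitting in the site. The pocket is cropped to the 50
protein residues with the smallest minimum heavy-atom distance to any
ligand heavy atom (`crop_pocket()`), ties at the boundary broken by residue
order so the crop is deterministic. Radius graphs use directed edges within
a 5 Å cutoff; the edge \((i,j)\) carries \(r_{ij} = X_j - X_i\) and the
message flows from \(j\) into the neighbourhood of \(i\).

### Frames and invariance

Scalar predictions are made invariant to rigid motions by frame averaging:
PCA of each graph's coordinates defines a centroid \(t\) and eigenbasis
\(u_1, u_2, u_3\) (eigenvalues descending), and the four SE(3) frames are
\([\alpha u_1, \beta u_2, (\alpha u_1)\times(\beta u_2)]\) over
\(\alpha,\beta \in \{-1,1\}\) — all proper rotations, so reflections are
*not* quotiented out and chirality remains visible. The E(3) variant
additionally enumerates the sign of the third axis (eight frames, improper
ones included) and is provided for the symmetry-group ablation, as is a
`none` setting that skips projection entirely. Each of the three graphs
receives its own frame set; the encoder runs once per frame and the
per-frame affinities are averaged.

Two numerical choices matter here. First, eigenvector sign from any solver
is arbitrary; we fix the global sign of each eigenvector (largest-magnitude
component positive) purely to stabilise frame *order* — the \(\alpha,\beta\)
enumeration makes the frame set itself sign-complete. Second, exactly
degenerate PCA spectra (planar or symmetric clouds) have no well-defined
eigenbasis; when an eigenvalue gap falls below \(10^{-8}\,\mathrm{tr}\,
\Sigma\) we add a deterministic, index-scaled jitter of
\(10^{-6}\,\mathrm{tr}\,\Sigma\) to the covariance diagonal and warn. Real
pockets are never exactly degenerate; synthetic tests can be.

Only frame-projected *directions* and rotation-invariant node attributes
(atomic numbers) are fed to the network; raw coordinates are not used as
features, since they would silently break the invariance the frame
construction provides.

### Encoder

Atomic numbers index a learned 128-dimensional embedding table. Each edge
is embedded from the Gaussian RBF expansion of its length (32 bases,
centers uniform on \([0, 5]\) Å, width equal to the spacing) concatenated
with its frame-projected unit direction, through a one-hidden-layer MLP
with swish activations. Separating the radial channel (RBF) from the
directional channel (unit vector) follows the usual design of
frame-averaged interatomic-potential encoders. Message passing runs for 4
layers; at layer \(l\) an enhanced convolution filter

\[
f^{(l)}_{ij} = \sigma\!\big(\mathrm{MLP}(e_{ij} \,\|\, h^{(l)}_i \,\|\,
h^{(l)}_j)\big)
\]

gates the neighbour state, and nodes update residually,
\(h^{(l+1)}_i = h^{(l)}_i + \mathrm{MLP}\big(\sum_{j\in N_i} h^{(l)}_j
\odot f^{(l)}_{ij}\big)\). Edge features are computed once per frame and
reused across layers; only node states evolve. A two-layer MLP head maps
final node states to scalar atomic energies. All hidden widths are 128; no
dropout or normalisation layers are used by default. One parameter set
serves all three graphs (`shared_weights = TRUE`); the
three-network variant exists only as an ablation, since separate encoders
break the cancellation argument above.

## Losses

Affinity labels in curated sets are skewed, so plain MSE is dominated by
the dense centre of the label distribution. The balanced MSE treats the
prediction as the mean of a Gaussian with learnable noise variance
\(\sigma^2\) and renormalises the likelihood over the training label
distribution; we realise the normalising integral with the batch labels as
the empirical distribution, giving a per-item log-softmax over
\(-(p_i-y_k)^2/2\sigma^2\). \(\sigma^2\) is stored as \(\log\sigma^2\)
(initial \(\sigma = 1\) pK) and learned jointly; its log is clamped to
\([-8, 8]\) as a guard against collapse of the likelihood scale.

Because ranking compounds by predicted affinity is the operation that
matters in screening, a listwise ranking term is added: a smooth NDCG with
sigmoid-approximated ranks (temperature 1 in label units; gains
\(2^{\mathrm{rel}}-1\) with labels min-shifted to be non-negative,
discounts \(1/\log_2(1+\mathrm{rank})\)), amplified as
\(\exp(\alpha(1-\mathrm{NDCG})) - 1 - \alpha(1-\mathrm{NDCG})\) with
\(\alpha = 1\) by default. The total loss is the sum of the two terms; for
batches of size one the ranking term is undefined and contributes zero.
The NDCG gain/discount conventions and \(\alpha\) are configurable because
no canonical values exist for them.

## Training

AdamW (decoupled weight decay \(10^{-4}\) on weight matrices only) with a
per-batch schedule: linear warm-up over the first two epochs from
\(10^{-6}\) to the peak rate, then cosine annealing to \(10^{-6}\). The
configured default peak is \(10^{-2}\). At the desk scale used throughout
this package (hundreds of complexes, 16 optimiser steps per epoch) that
peak is reached after only ~30 steps and destabilises AdamW — whose update
magnitude per parameter is essentially the learning rate itself — so the
worked examples and the acceptance experiments train with a peak of
\(5\times10^{-3}\) and a global gradient-norm clip of 5. Batch size 32;
the best-validation-RMSE parameters are the ones returned.

The compiled kernels run in single precision (the standard for this model
class) while parameters and optimiser state remain double; a double
instantiation of the same kernels backs the exact verification tests
against the plain-R reference implementation. Training is seeded and
reproducible on CPU, and `run_seeds()` repeats train/evaluate over several
seeds and reports mean ± sd, the convention used for all headline numbers.

## Synthetic data and what the tests show

`synthetic_spec()` / `make_dataset()` generate labelled complexes without
any downloads. A protein is a self-avoiding chain of residue clusters
(centres 4.5–5.5 Å apart, 3–4 heavy atoms per residue scattered with 1 Å
sd); the ligand is a compact cluster placed so the minimum protein–ligand
heavy-atom distance lies between 3.0 and 4.0 Å, guaranteeing cross-molecule
edges inside the 5 Å cutoff. Elements are drawn from {C, N, O, S} with
roughly organic frequencies. The oracle label is an affine map of the
negated sum, over cross-molecule pairs within 5 Å, of a truncated-and-
shifted Lennard-Jones-style well \(g(d) = \varepsilon[(r_0/d)^{12} -
2(r_0/d)^6]\) with \(r_0 = 3.6\) Å and per-element depths combined by
geometric mean, plus Gaussian noise of 0.3 pK. The affine constants
(centre 4.0, scale 0.9) were fixed once so labels land on a PDBbind-like
pK range (roughly 2–12, sd ≈ 2); the clash floor of 3.0 Å keeps the
\(r^{-12}\) branch bounded. The label is exactly a sum of atomic
contributions, so the model class can represent it and parameter recovery
is a meaningful test.

The default problem sizes — 5–8 residues per protein, 4–6 ligand atoms,
625 complexes split 500/50/75, 18 training epochs — are the package's
desk-scale study conditions: small enough that the full recovery
experiment, including the framework-off ablation, runs in minutes on one
CPU core, large enough that the held-out Pearson correlation of the
recovered model exceeds 0.9. What passing recovery shows is that the
architecture, losses, optimiser and invariance machinery can jointly
identify an additive short-range pairwise potential from structures alone.
What it does not show: performance on real complexes, whose energetics
include solvation, entropy, long-range electrostatics and conformational
strain that the oracle deliberately lacks, and whose geometry (secondary
structure, packing, chemistry of real residues) the generator does not
imitate. The synthetic oracle is also achiral (pair distances only), so
SE(3) and E(3) variants should — and do — perform alike on it; chirality
sensitivity is asserted structurally (a mirrored input changes an SE(3)
prediction and leaves an E(3) one unchanged) rather than through labels.

## Degenerate inputs and edge cases

Single-atom graphs have no edges; the empty neighbourhood sum is the zero
vector and the update reduces to a learned constant per layer. Batches of
size one skip the ranking term. Constant predictions make the Pearson
correlation undefined; evaluation reports `NA` with a `degenerate` flag
rather than silently writing 0. Contributions written to the B-factor
column of an annotated PDB are clipped to the field's numeric range by a
power-of-ten scale recorded in a `REMARK` line.

## Known limitations

* The unbound state is the bound pose; relaxation effects are invisible.
* Bond topology, protonation and charges are ignored by design — the
  model consumes atomic numbers and coordinates only.
* The pocket cap counts residues, not atoms, so atom counts vary between
  complexes; the 50-residue default follows standard pocket-cropping
  practice.
* Frame averaging multiplies encoder cost by the frame count (4 for SE(3),
  8 for E(3)).
* The desk-scale acceptance experiments quantify recovery of a synthetic
  additive potential, not benchmark performance on experimental affinity
  data.
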