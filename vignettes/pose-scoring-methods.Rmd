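---
title: "Scoring antibody-antigen binding poses with equivariant graph networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring antibody-antigen binding poses with equivariant graph networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(abpose)
```

## The problem

Docking and generative structure-prediction tools emit many candidate
arrangements ("poses") of an immunoglobulin bound to an antigen, most of
which are wrong. Ranking those candidates requires two judgements: a binary
one — is this pose native-like at all? — and a graded one — how close is it
to the native complex on the DockQ scale? `abpose` implements both as
learnable functions of an interface-focused residue graph:

* a **classifier** returning the probability that a pose is native-like
  (DockQ at or above 0.8 against the true complex, boundary inclusive), and
* a **regressor** estimating the DockQ value itself through a scaled-tanh
  head bounded in (0, 1).

Candidate selection composes the two: the classifier filters out predicted
non-binders, the regressor ranks the survivors, and precision@K summarises
the quality of the short list (`topk_success()`).

## From structure to graph

A complex is parsed from PDB or mmCIF (`parse_structure()`), cleaned by the
standard curation rules — HETATM/non-standard residues removed, the
highest-summed-occupancy altloc retained per residue with file-order
tie-break (`clean_structure()`) — and each chain is assigned a role
(`assign_roles()`): `ig_heavy`, `ig_light`, `nanobody`, `scfv`,
`tcr_alpha`, `tcr_beta` on the Ig side; `antigen`, `mhc`, `peptide` on the
antigen side. CDR intervals are consumed from an annotation table in author
numbering; the package does not renumber sequences.

`build_graph()` places one node per residue. Edges come in two kinds, both
defined on the **minimum heavy-atom distance** between residues:

* *intra* edges within a side at `tau_intra` = 3.5 Å or less (a side may
  span several chains — heavy plus light, or MHC plus peptide);
* *inter* edges across the interface at `tau_inter` = 10 Å or less.

Both boundaries are inclusive. Each edge carries three raw distances —
minimum-atom, Cα–Cα, and centroid–centroid — expanded by a Gaussian RBF
map with D = 10 length scales log-spaced inclusively over [0.25, 8] Å
(`rbf_expand()`), giving 30 features per edge. We read "log-spaced scales"
as Gaussian *widths* with zero centers, `exp(-d²/2s_k²)`; a log-spaced
*centers* variant is available via `rbf_mode = "centers"` since the phrase
admits both readings. Distances use heavy atoms by default
(`include_hydrogens = FALSE`): hydrogen placement varies wildly between
sources, and heavy-atom-only distances make featurization independent of
protonation; the flag restores file hydrogens if a consistently protonated
corpus is available. Centroids are unweighted means of heavy-atom
coordinates (`mass_weighted = TRUE` switches to mass weighting).

Node features are 320-wide per-residue embeddings. The built-in
`hashed_embedder()` maps each residue identity (a sliding window of length
1 by default) through a fixed hash-seeded linear-congruential stream to a
reproducible pseudo-random vector with unit component variance — the same
shape as a small protein-language-model embedding, with no download and no
global-RNG interaction. A precomputed embedding matrix (e.g. from an
external protein language model) can be passed wherever an embedder is
accepted; the encoder validates its width against `input_dim`.

The node coordinate for the equivariant network is the Cα position
(centroid fallback) — a residue must be a single point and the Cα is the
conventional choice.

## Interface subgraph sampling

Whole complexes waste computation on residues far from the binding site.
`sample_subgraph()` extracts the k-hop neighbourhood (default 3 hops) of a
seed set — the unique endpoints of inter edges, or the CDR residues in
`seed_mode = "cdr"` — by breadth-first expansion over both edge kinds,
stopping once the node count would exceed the cap of 600. Within the
violating hop, nodes are admitted in ascending index order until the cap is
reached exactly; the same rule truncates an oversized seed set. Sampling is
deterministic: there is no RNG anywhere in the sampler. The two seed modes
double as the training-time graph-level augmentation knob. Poses whose
interface is empty (a far-displaced decoy) cannot be seeded; the benchmark
generator and the prediction pipeline keep such graphs whole (capped)
rather than failing, so the model can see the tell-tale absence of
inter-side edges.

## The network

The encoder maps node features to a hidden width h = 64 with a SiLU
projection, then applies T = 4 blocks of E(n)-equivariant message passing,
each followed by a GRU gate:

* **EGNN layer** (`egnn_layer()`): per directed edge,
  `m_ij = φ_e(h_i, h_j, d_ij², e_ij)`; coordinates update as
  `p_i' = p_i + (1/deg i) Σ_j (p_i - p_j)/(d_ij + 1) · φ_x(m_ij)` and
  features as `h̃_i = φ_h(h_i, Σ_j m_ij)`. The MLPs are two-layer with
  SiLU; the final coordinate-MLP layer is zero-initialised so coordinates
  start unchanged. Two numerical choices keep activations on a common
  scale: the squared distance enters φ_e in units of the interface cutoff
  (d²/100), and the coordinate update uses unit-normalised difference
  vectors — both standard stabilisations that preserve equivariance
  exactly.
* **GRU gate** (`gru_gate()`): a standard GRU cell whose input is the
  concatenation `[h̃_i | h_i]` and whose hidden state is `h_i`, acting as a
  learnable gated residual that counters over-smoothing. The update-gate
  bias is initialised at +2 so the gate starts biased toward the identity
  path (the same reasoning as an LSTM forget-gate bias of 1); without it
  the convex combination `(1-z)n + z h` contracts feature magnitude by
  roughly half per layer at initialisation.

Scalar features are rigid-motion invariant and coordinates equivariant by
construction; the test suite asserts both numerically, along with node-
permutation invariance of graph-level outputs.

The readout (`pool_weighted()`) is a sigmoid-gated **weighted sum** (not a
mean) over a selected node subset. All seven selection strategies are
implemented (`select_pool_set()`): all nodes (the default), interface only,
CDR-epitope only, CDR only, and the three complements. An empty selection
raises an explicit error directing the caller to `all_nodes` — never a
silent fallback. The classifier head is a two-layer SiLU MLP with softmax
over (non-native, native-like) and dropout 0.1 between its layers at
training time; the regressor head is `(tanh(0.5 z) + 1)/2`. An auxiliary
linear node head predicts the node type (antigen / heavy / light;
nanobody, scFv and TCRα count as heavy, TCRβ and light chains as light).
Predictions from several models or checkpoints combine by a validated
convex weighted average (`ensemble_combine()`).

## Objectives

The classifier minimises `L = L_GC + α·L_NC + β·L_MDN` with α = 1e-3 and
β = 2e-3: graph-level cross-entropy, the auxiliary node-type
cross-entropy, and the negative Pearson correlation between predicted
native-like probability and the true DockQ over the minibatch. The
correlation is computed per minibatch — the only well-defined option
online — and a batch with constant DockQ contributes zero rather than NaN.
`L_NC` averages the per-graph node means so every graph weighs equally
regardless of size.

The regressor minimises `L = -corr(y, ŷ) + L_rank`, where `L_rank` is the
top-one listwise (ListNet) ranking loss at temperature 1: per group,
`-Σ softmax(y)·log softmax(ŷ)`, averaged over groups. Groups default to
"examples sharing a target complex", falling back to the whole batch when
a minibatch happens to draw singletons. Both losses are implemented twice:
as plain numeric functions (`classifier_loss()`, `regressor_loss()`, the
documented API) and as differentiable tape graphs used in training; the
tests assert the two agree and that analytic gradients match finite
differences to 1e-4 relative.

All gradients come from a small reverse-mode automatic-differentiation
tape written for this package (dense matrices, the op set the encoder
needs); there is no external deep-learning runtime.

## Training protocol

`train()` runs Adam with an initial learning rate annealed by a cosine
schedule whose endpoints are exact (`cosine_lr()`: epoch 1 gives
`lr_init`, the final epoch `lr_min`), class-weighted minibatch sampling
with replacement (weights 0.8 for negatives, 0.2 for positives; a
single-class set warns and falls back to uniform), global gradient-norm
clipping at 5, and early stopping on the validation metric — F1 at
threshold 0.5 for the classifier, Pearson r for the regressor — with
patience 10. Ties in the monitored metric refresh the incumbent checkpoint
(later epochs win) but do not reset patience; this matters early in
training when F1 at a fixed 0.5 threshold can sit at zero for several
epochs while the ranking is already improving. The five best-validation
checkpoints are retained and `predict()` averages them uniformly by
default (checkpoint-averaging ensemble); explicit weights pass through
`ensemble_combine()`.

The default schedule (1e-4 annealed to 1e-5 over up to 50 epochs) is the
deployment-scale protocol, appropriate for corpora with tens of thousands
of poses and hundreds of optimiser steps per epoch. The desk-scale
benchmark below takes only ~75 steps per epoch, so its training runs use a
proportionally larger rate (3e-3 to 5e-3 annealed by the same cosine
rule over 10 epochs); with 1e-4 the parameters simply cannot move far
enough in 750 steps to leave the initialisation basin. The schedule shape,
optimiser, sampler weights, clipping and early-stopping logic are
identical in both regimes.

The regressor fine-tunes on cognate poses (natives and perturbed decoys).
Non-cognate pairings carry DockQ 0 *by convention* — the score is not
computable for a pair with no native reference — so a grazing non-cognate
pose whose geometry sits mid-range anchors the correlation term to a
label that does not describe its structure; at desk scale this measurably
degrades the fitted correlation (held-out r drops from ~0.86 to ~0.75 in
our runs). They remain first-class negatives for the classifier, whose
loss never interprets their DockQ geometrically.

`init_from_classifier()` implements classifier-to-regressor transfer: all
encoder, pooling and auxiliary-head parameters are copied (the test suite
checks the encoder outputs are bit-identical), the softmax head is
discarded, a fresh scaled-tanh head is attached, and everything remains
trainable.

## The synthetic benchmark

`build_benchmark()` makes the whole pipeline testable on a laptop with no
downloads. Each native complex is two pseudo-residue chains (backbone
N/Cα/C/O plus one side-chain pseudo-atom, so minimum-atom, Cα and centroid
distances genuinely differ and backbone RMSDs are well defined) laid on
smooth random curves and posed with at least ten cross-side residue
contacts within 5 Å. Antigens come from `n_clusters` = 10 generator
families (a shared family curve and sequence, with small per-complex
jitter), which supplies the cluster structure for leakage-free splits.
Synthetic CDR intervals are the Ig residues within 8 Å of the antigen, so
all seven pooling strategies have non-trivial masks.

Decoys apply a rigid rotation and translation to the Ig side plus per-atom
Gaussian noise, one per row of the perturbation schedule, and each is
labelled by `dockq()` against its native. The default schedule spans DockQ
across (0, 1) with three near-native entries above 0.8 and five displaced
entries below ~0.35. Translations act mainly along the local dissociation
axis (from the antigen-side to the Ig-side interface atoms): pulling the
binder off the epitope is what degrades an interface, and it is this
choice that makes the benchmark *separable by construction* — a decoy
translated tangentially can keep a native-sized contact count while its
DockQ collapses, which no geometric model could detect. Rotations in the
negative entries are kept moderate (5–20°) for the same reason: large
rotations about the interface centroid swing distal residues back into
contact. Non-cognate examples pair an Ig from a different antigen family
with the target antigen, posed deliberately loosely (grazing the epitope
at clearance ≥ 4.5 Å) because non-cognate pairs lack shape
complementarity; they carry label 0 and DockQ 0 by convention.

What the generator does *not* emulate: side-chain packing, clashes and
their refinement, conformational (non-rigid) decoy error, binding-funnel
energetics, and real evolutionary couplings between binder and target
sequences (the hashed embeddings carry sequence identity but no
co-evolution). Passing the learnability checks therefore demonstrates that
the architecture, objectives and training loop can extract interfacial
geometry — not that the model would reach any particular accuracy on real
antibody-antigen corpora.

`split_by_cluster()` assigns whole antigen clusters to train/validation/
test toward 6:2:2 by a seeded largest-first greedy balance; ten equal
clusters split exactly 6/2/2, and skewed sizes stay within ±10 points of
the targets.

## DockQ

`dockq()` follows the external standard: Fnat over native cross-side
residue contacts at 5 Å (any heavy-atom pair); LRMS as the Ig-side
backbone RMSD after least-squares superposition of the antigen-side
backbones; iRMS over the 10 Å native-interface residues after
superposition on those residues; combined as
`(Fnat + 1/(1+(iRMS/1.5)²) + 1/(1+(LRMS/8.5)²))/3`. Multi-chain sides are
merged before comparison, backbone atoms are N/Cα/C/O, and superpositions
use an SVD-based least-squares fit. The constants are the published DockQ
standard; the test suite verifies the implementation against an
independently coded reference built on a different superposition routine.
`label_from_dockq()` applies the boundary-inclusive 0.8 rule.

Classification metrics follow the usual conventions with two documented
choices: AUC by the rank statistic with ties averaged (equal to
brute-force pair counting), and AP by step-wise summation over unique
score thresholds (precision at each recall change, no interpolation —
conventions differ between libraries, so the tests pin this one against an
enumeration oracle). Undefined metrics (single-class inputs, constant
vectors) are `NA` sentinels, never silent zeros. `select_threshold_fbeta()`
scans observed scores and resolves ties toward the lowest threshold.

## Numerical and design notes

* Altloc ties (equal summed occupancy) keep the first label in file
  order.
* Non-standard residues (including MSE) are dropped, not converted: no
  conversion rule is defined, and dropping is conservative.
* Edge construction prefilters residue pairs by centroid distance and
  bounding radii before exact minimum-atom distances, and equals the
  brute-force all-pairs oracle exactly.
* `topk_success()` keeps K in the denominator when fewer than K survivors
  remain (missing slots count as failures) and flags the truncation;
  survivor ties break by classifier score, then input order.
* Structure and graph containers are plain S3 lists; tabular surfaces
  (manifests, prediction tables, metric reports, training history) are
  tibbles, with `tidy()`/`glance()`/`autoplot()` for fitted models. A
  fully data-frame-first organisation does not fit residue graphs and
  parameter sets, so the package keeps the container style of structural-
  bioinformatics packages for those.
* Problem sizes used in the shipped checks: the learnability benchmark is
  100 complexes x (1 native + 8 decoys + 1 non-cognate) with 30-residue
  chains; module tests use 12-16-residue chains. These sizes make the
  full suite run in minutes on one CPU core while leaving every
  interface-geometry property intact.

## Known limitations

* The built-in embedder carries no evolutionary information; plug in a
  real protein-language-model matrix for production use.
* Pseudo-residue fixtures cannot probe side-chain-level effects such as
  clash penalties or rotamer errors.
* The regressor's correlation term is batch-coupled, so very small batch
  sizes make its gradient noisy; gradient clipping guards this.
* Single-model uncertainty is not estimated; checkpoint averaging is the
  only ensembling provided, matching the deployment recipe.
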