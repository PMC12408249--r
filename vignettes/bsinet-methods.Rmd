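---
title: "Predicting biotech-small-molecule interactions with graph attention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting biotech-small-molecule interactions with graph attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Drug-drug interaction prediction is usually studied between pairs of small
molecules. Interactions between a *biotech* drug — a protein therapeutic
described by one or more amino-acid chains — and a small molecule are harder:
the two populations have incommensurate structural representations (a SMILES
string versus protein chains), and public corpora annotate such pairs
sparsely. `bsinet` casts the task as multiclass classification: given a
(small-molecule, biotech) pair, predict which of C interaction classes it
belongs to, where class 0 is the negative (non-interacting) class and the
remaining classes are distinct interaction types.

## The model

Each drug pair is represented by the concatenation of four blocks:

1. **Graph branch (width 512).** The SMILES string becomes a bidirected
   heavy-atom graph; every bond contributes both directed edges and every
   atom carries one self-loop, which keeps each attention neighborhood
   non-empty. Two multi-head graph attention layers encode the graph. Per
   head with weight matrix $W$ and attention vector $a$,
   $$e_{ij} = \mathrm{LeakyReLU}\!\left(a^\top [W h_i \,\|\, W h_j]\right),
   \qquad
   \alpha_{ij} = \frac{\exp e_{ij}}{\sum_{k \in N(i)} \exp e_{ik}},
   \qquad
   h_i' = \sigma\!\Big(\sum_{j \in N(i)} \alpha_{ij} W h_j\Big).$$
   Heads are concatenated: layer 1 uses 4 heads of width 128 (per-node
   width 512), layer 2 uses 4 heads of width 256 (width 1024). Each layer
   is followed by per-node layer normalization and feature dropout
   (rate 0.2). A per-node fully connected layer maps 1024 to 512 and mean
   pooling over atoms yields the 512-wide drug vector.
2. **Fused small-molecule similarity row (width = number of small
   molecules; 2148 at the reference corpus scale).** SSf = SSI + SST + SSs,
   the elementwise (unscaled) sum of the binary drug-drug interaction
   matrix, the cosine similarity between drug-target interaction profiles,
   and the Tanimoto similarity between circular fingerprints.
3. **Sequence embedding (width 1024).** Each chain of the biotech drug is
   embedded by a pluggable sequence embedder and chains are averaged
   without weights, so chain order never matters.
4. **Fused biotech similarity row (196 at the reference scale).**
   BBf = BBI + BBT + BBs, with BBs the normalized global-alignment
   similarity between concatenated chains.

Blocks 1+2 form the small-molecule vector (512 + 2148 = 2660), blocks 3+4
the biotech vector (1024 + 196 = 1220); their concatenation (3880) feeds an
MLP with two ReLU hidden layers (defaults 2048 and 512) and a softmax over
the C = 32 classes. Training minimizes multiclass cross-entropy
$-\sum_i y_i \log p_i$ with Adam (learning rate $10^{-3}$), minibatches of
256, and an epoch loop that stops once the epoch mean training loss drops
below $\varepsilon = 0.05$ or after 10 epochs.

The whole network — attention layers, normalization, dropout, pooling,
classifier — is implemented directly as matrix operations with manual
backpropagation; a test verifies the analytic gradients against central
finite differences at relative error below $10^{-4}$. For speed, all
molecular graphs in a dataset are stacked into one disconnected batch graph
so a single attention pass covers every molecule.

## Parameter choices the architecture leaves open

Several details are genuinely open in the design; the
package fixes each one once, exposes it in `bsinet_config()`, and documents
the default:

* **LeakyReLU slope 0.2** in attention scores — the canonical choice for
  graph attention.
* **Hidden activation** $\sigma$: the exponential linear unit. Any fixed
  rectifier works here; ELU keeps gradients alive for the negative
  pre-activations that attention aggregation produces early in training
  (`activation = "relu"` or `"identity"` are available).
* **Second layer head count 4**, matching the first layer by symmetry
  (only the first layer's head count is stated).
* **Normalization between layers**: per-node layer normalization. Batch
  statistics are ill-defined across variable-size graphs, so a per-node
  scheme is the safe reading of "normalization" (`normalization = "none"`
  disables it).
* **Dropout placement**: on node features after each normalization, not on
  attention coefficients, and not inside the classifier MLP — matching the
  stated "normalization and a dropout layer ... to the node features".
* **Classifier hidden widths (2048, 512)**: deliberately generic,
  chosen once and config-overridable; a grid-search helper is out of scope.
* **FC-then-pool order** in the graph branch: per-node 1024 to 512 followed
  by mean pooling is the minimal wiring that produces the stated 512-wide
  drug vector.

## Featurization choices

* **Atom features (width 28)**: one-hot element
  {C, N, O, S, F, Cl, Br, I, P, other}, one-hot degree 0-5, formal charge,
  aromatic flag, ring flag, one-hot hybridization {sp, sp2, sp3, other},
  one-hot total hydrogens 0-4. Hydrogens stay implicit and stereochemistry
  is ignored: attention operates on heavy-atom connectivity.
  Aromaticity and rings come from the parser's ring perception;
  hybridization is derived from bond orders (triple or two doubles - sp;
  double or aromatic - sp2; otherwise sp3); implicit hydrogen counts follow
  standard valences with charge adjustment.
* **Fingerprints**: circular (Morgan/ECFP4-style), radius 2, 2048 bits,
  built by iterative neighborhood hashing over atom descriptor tuples and
  bond orders. Tanimoto similarity is computed on the set-bit indices.
* **Global alignment**: Needleman-Wunsch under BLOSUM62 with affine gaps
  (opening 10, extension 1), normalized as
  $s_{ij}/\sqrt{s_{ii}\,s_{jj}}$ and clipped to $[0,1]$ — a symmetric,
  self-normalizing score with self-similarity exactly 1. Multi-chain drugs
  are aligned on their concatenated chains (the averaging rule applies only
  to embeddings).
* **Degenerate rows**: a drug with an empty fingerprint or no recorded
  targets scores similarity 0 against everything *including itself* — the
  absence of evidence is not evidence of identity, and this avoids 0/0.
* **Sequence embedder**: the shipped `stub_embedder()` hashes 3-mer
  composition into 1024 buckets with seed-salted signs and L2-normalizes.
  It preserves the real embedder's interface, width, and determinism, and
  separates sequences of different composition, but captures none of the
  contextual information a pretrained protein language model learns. Any
  object with an `embed(chain)` function and a `d_emb` field (for example
  a wrapper around a real language model run offline) can be swapped in;
  every downstream tensor shape is unchanged.

## Evaluation protocol

Stratified k-fold cross-validation (default k = 10; the learnability checks
use k = 2) deals each class's examples round-robin after a seeded shuffle,
so per-fold class counts deviate from exact proportionality by at most one
example per class; classes with fewer than k examples are rejected loudly.
Out-of-fold predictions are pooled and scored once, and per-fold metrics
are reported as mean and standard deviation across folds.

Metrics come in three regimes. *Micro* scores the pooled confusion matrix —
precision, recall, F1 and accuracy coincide there, which the suite asserts —
with MCC computed as the multiclass correlation coefficient of the matrix.
*Macro* is the unweighted mean of per-class one-vs-rest metrics; *weighted*
is the support-weighted mean. AUROC uses the midrank Mann-Whitney
formulation and AUPR is step-wise average precision, each one-vs-rest and
aggregated per regime (micro flattens all indicator/score pairs into one
curve). Classes absent from the test labels are skipped in macro/weighted
ranking metrics with a warning.

The comparator models — SVM (calibrated probabilities), random forest
(probability forest), XGBoost (softprob), a three-layer MLP and a 1-D CNN
of three convolution + batch-normalization + dropout blocks — all consume
the identical fold plan and feature rows (the concatenation of the drug
pair's SSf and BBf rows, 2344-wide at the reference scale) and are scored
by the same metrics code path. CNN sizes (kernel 7, channels 16/32/64,
stride 2, dropout 0.2) follow the cited three-block structure, which states
the layer types but not their sizes.

## The synthetic corpus

Real drug-interaction corpora derive from licensed databases and cannot be redistributed, so the package
ships a generator whose output exercises every pipeline stage with known
ground truth. Both drug populations are partitioned into latent clusters
(default 4): small molecules are drawn per cluster from one scaffold family
(aliphatics, substituted benzenes, ethers/esters, amines/amides) with
enumerated substituent edits, so within-cluster Tanimoto similarity exceeds
between-cluster similarity by construction; biotech sequences interleave
three per-cluster 12-residue motifs with random linkers at 10% per-position
mutation, giving the same property under alignment; drug-target and
drug-drug edges concentrate within cluster blocks so the interaction-derived
similarities are informative too. The pair label is a deterministic
function of the (small-molecule cluster, biotech cluster) combination:
a `negative_fraction` of combinations map to the negative class and the
rest are dealt to positive classes with geometrically shrinking shares,
producing the long-tailed class distribution that stresses stratification
and weighted metrics. `label_noise` (default 0.05; 0 in the learnability
checks) flips labels to a random other class.

Defaults are 120 small molecules, 30 biotech drugs, 64 targets (split 3:1
between the two target universes), 8 classes — sizes at which the full
pipeline trains in minutes on one CPU while leaving every class at least
k examples for stratification. What passing on this corpus shows is that
the pipeline can recover a planted, cluster-determined signal end-to-end;
it does not show performance on real pharmacological data, whose label
structure is not a clean function of structural clusters.

## Numerical safety and degenerate inputs

Softmaxes (attention and classifier) subtract the row maximum before
exponentiation; cross-entropy clamps probabilities at $10^{-12}$;
single-atom molecules are valid graphs thanks to self-loop augmentation;
an unparsable or empty SMILES string fails with the offending string in
the message; empty sequences, dangling edge identifiers, and labels outside
a frozen vocabulary are all rejected by name. The label vocabulary is
frozen in sorted order with the negative class pinned to index 0, and every
matrix is stored with an id sidecar so row order is never positional.

## Known limitations

* The stub embedder is a compositional hash, not a language model; absolute
  performance with it says nothing about what pretrained embeddings add.
* Attention uses node features only; bond features (order, conjugation)
  enter the graph only through the atom descriptors.
* The generator's chemistry is template-based and far narrower than a real
  drug corpus; alignment and fingerprint similarities are correspondingly
  easier than in the wild.
* Training is plain R matrix algebra on one CPU: adequate for corpora of a
  few hundred drugs, not for large-scale screening.
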