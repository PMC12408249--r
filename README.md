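# bsinet

Multiclass interaction prediction for **biotech–small-molecule drug
pairs**. A biotech drug is a protein therapeutic described by one or more
amino-acid chains; a small molecule is described by a SMILES string. Given
a pair, the package predicts which of C interaction classes it belongs to
(class 0 = no interaction, the rest distinct interaction types), for
researchers studying polypharmacy risks between the two drug populations.

## The model

Each pair is encoded as the concatenation of four blocks:

- **Graph branch (512)** — the SMILES string becomes a bidirected
  heavy-atom graph with self-loops; two multi-head graph attention layers
  (4 heads × 128, then 4 heads × 256, heads concatenated) with per-node
  layer normalization and dropout 0.2, a per-node fully connected layer,
  and mean pooling produce a 512-wide drug vector. Per head:

  e_ij = LeakyReLU(aᵀ[W h_i ‖ W h_j]),
  α_ij = softmax_{j∈N(i)}(e_ij),
  h′_i = σ(Σ_{j∈N(i)} α_ij W h_j)

- **SSf row (2148 at full corpus scale)** — SSf = SSI + SST + SSs: the
  small-molecule interaction matrix, cosine similarity of drug–target
  profiles, and Tanimoto similarity of circular fingerprints, summed
  elementwise.
- **Sequence embedding (1024)** — per-chain embeddings from a pluggable
  embedder (an offline k-mer stub ships with the package), averaged over
  chains.
- **BBf row (196 at full scale)** — BBf = BBI + BBT + BBs, with BBs the
  normalized BLOSUM62 global-alignment similarity.

Small-molecule side: 512 + 2148 = 2660. Biotech side: 1024 + 196 = 1220.
The 3880-wide pair vector feeds a two-hidden-layer MLP with a softmax over
32 classes, trained with Adam on cross-entropy (−Σ y_i log p_i) under
stratified k-fold cross-validation. Metrics are reported in micro, macro,
and support-weighted regimes (precision/recall/F1, multiclass MCC,
one-vs-rest AUROC/AUPR). SVM, random forest, XGBoost, MLP, and 1-D CNN
comparators run on the concatenated SSf‖BBf rows through the same folds
and scoring code. The attention network — forward and backward passes —
is implemented in plain R matrix algebra and gradient-checked against
finite differences in the test suite.

## Worked example

The package ships a synthetic-corpus generator with a planted,
cluster-determined label rule, so the whole pipeline runs without any
external data:

```r
library(bsinet)

corpus  <- generate_corpus(synthetic_config(seed = 1, label_noise = 0))
dataset <- assemble_dataset(corpus)

print(dataset$graphs[[1]])
#> <molecular_graph SM0001: 5 atoms, 8 directed bond edges, d_atom=28>

cfg <- config_for_dataset(dataset)
cfg$pair_width
#> [1] 1686    # 512 + 120 + 1024 + 30 at synthetic scale

res <- run_cv(dataset, k = 2, seed = 1, model = "random_forest")
w <- res$pooled$weighted
sprintf("weighted precision %.4f recall %.4f F1 %.4f AUROC %.4f AUPR %.4f",
        w$precision, w$recall, w$f1, w$auroc, w$aupr)
#> "weighted precision 1.0000 recall 1.0000 F1 1.0000 AUROC 1.0000 AUPR 1.0000"
```

The perfect score is expected here: with `label_noise = 0` the synthetic
label is an exact function of the two drugs' latent clusters, and the
fused similarity rows expose those clusters. Swap
`model = "bsinet"` to train the attention network itself (about 3 minutes
on one CPU; it reaches the same weighted F1 on this corpus), or
`svm` / `xgboost` / `mlp3` / `cnn3` for the other comparators.
`res$fold_summary` carries per-fold means and standard deviations,
`res$loss_traces` the per-epoch training losses.

A command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/bsinet", package="bsinet"))')" \
  simulate --out corpus/ --seed 1
# then: featurize / train / evaluate / predict
```

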