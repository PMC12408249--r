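# Shared small corpus/dataset fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

tiny_corpus <- function() {
  if (is.null(.fixture_cache$corpus)) {
    .fixture_cache$corpus <- generate_corpus(synthetic_config(
      n_small = 24L, n_biotech = 12L, n_targets = 16L, n_classes = 4L,
      n_clusters = 2L, label_noise = 0, negative_fraction = 0.25,
      seed = 11L
    ))
  }
  .fixture_cache$corpus
}

tiny_dataset <- function() {
  if (is.null(.fixture_cache$dataset)) {
    .fixture_cache$dataset <- assemble_dataset(tiny_corpus(),
                                               embedder = stub_embedder(64L))
  }
  .fixture_cache$dataset
}

# a small trained-ish model over the tiny dataset (1 epoch) for contract
# tests that need non-degenerate parameters
tiny_model <- function() {
  if (is.null(.fixture_cache$model)) {
    ds <- tiny_dataset()
    cfg <- config_for_dataset(ds, gat1_out = 8L, gat1_heads = 2L,
                              gat2_out = 8L, gat2_heads = 2L,
                              fc_out = 16L, mlp_hidden = c(32L, 16L),
                              max_epochs = 1L, batch_size = 64L)
    net <- bsinet_init(cfg, ds$d_atom, seed = 3L)
    .fixture_cache$model <- train_fold(net, ds, seq_len(nrow(ds$pairs)),
                                       seed = 3L)$model
  }
  .fixture_cache$model
}
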