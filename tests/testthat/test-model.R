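test_that("the width contract chain holds at reference defaults", {
  cfg <- bsinet_config()
  expect_equal(cfg$gat1_heads * cfg$gat1_out, 512L)
  expect_equal(cfg$fc_out + cfg$ssf_width, 2660L)
  expect_equal(cfg$emb_width + cfg$bbf_width, 1220L)
  expect_equal(cfg$pair_width, 3880L)
  expect_equal(cfg$n_classes, 32L)

  # generalizes to arbitrary configs
  cfg2 <- bsinet_config(fc_out = 8L, ssf_width = 10L, emb_width = 6L,
                        bbf_width = 4L, mlp_hidden = c(16L, 8L),
                        n_classes = 5L)
  expect_equal(cfg2$pair_width, 8L + 10L + 6L + 4L)
})

test_that("side vectors concatenate in the documented order", {
  expect_equal(small_molecule_vector(c(1, 2), c(3, 4, 5)), c(1, 2, 3, 4, 5))
  expect_equal(biotech_vector(c(9, 8), c(7)), c(9, 8, 7))
  cfg <- bsinet_config(fc_out = 2L, ssf_width = 3L, emb_width = 2L,
                       bbf_width = 1L, mlp_hidden = c(4L, 4L))
  expect_error(small_molecule_vector(c(1, 2, 3), c(1, 2, 3), cfg), "fc_out")
  expect_error(biotech_vector(c(1), c(1), cfg), "emb_width")
})

test_that("graph branch outputs fc_out-wide vectors, even for one atom", {
  cfg <- bsinet_config(gat1_out = 4L, gat1_heads = 2L, gat2_out = 4L,
                       gat2_heads = 2L, fc_out = 6L, ssf_width = 3L,
                       bbf_width = 2L, emb_width = 4L, n_classes = 3L,
                       mlp_hidden = c(8L, 8L))
  model <- bsinet_init(cfg, d_atom = 28L, seed = 5L)
  v <- graph_branch(model, smiles_to_graph("CCO"))
  expect_length(v, 6L)
  v1 <- graph_branch(model, smiles_to_graph("C"))   # self-loop only
  expect_length(v1, 6L)
  expect_true(all(is.finite(v1)))
})

test_that("mean pooling over identical per-node outputs is that output", {
  g <- smiles_to_graph("CCCC")
  batch <- build_graph_batch(list(g))
  F_ <- matrix(rep(c(1.5, -2, 0.25), each = 4), 4, 3)
  pooled <- rowsum(F_, batch$node_graph) / batch$graph_sizes
  expect_equal(as.vector(pooled), c(1.5, -2, 0.25))
})

test_that("forward returns a probability simplex and is deterministic", {
  cfg <- bsinet_config(gat1_out = 4L, gat1_heads = 2L, gat2_out = 4L,
                       gat2_heads = 2L, fc_out = 6L, ssf_width = 3L,
                       bbf_width = 2L, emb_width = 4L, n_classes = 7L,
                       mlp_hidden = c(8L, 8L))
  model <- bsinet_init(cfg, d_atom = 28L, seed = 5L)
  pair <- list(graph = smiles_to_graph("CCN"), ssf_row = c(0.2, 1.1, 0),
               emb = c(0.1, -0.2, 0.3, 0), bbf_row = c(1, 0.5))
  p1 <- bsinet_forward(model, pair)
  p2 <- bsinet_forward(model, pair)
  expect_length(p1, 7L)
  expect_true(all(p1 > 0))
  expect_equal(sum(p1), 1, tolerance = 1e-6)
  expect_identical(p1, p2)
  expect_error(bsinet_forward(model, modifyList(pair, list(emb = c(1, 2)))),
               "width")
})

test_that("zero final-layer weights give the uniform distribution", {
  cfg <- bsinet_config(gat1_out = 4L, gat1_heads = 2L, gat2_out = 4L,
                       gat2_heads = 2L, fc_out = 6L, ssf_width = 3L,
                       bbf_width = 2L, emb_width = 4L, n_classes = 32L,
                       mlp_hidden = c(8L, 8L))
  model <- bsinet_init(cfg, d_atom = 28L, seed = 5L)
  model$params$mlp$W3 <- model$params$mlp$W3 * 0
  model$params$mlp$b3 <- model$params$mlp$b3 * 0
  pair <- list(graph = smiles_to_graph("CCN"), ssf_row = c(0.2, 1.1, 0),
               emb = c(0.1, -0.2, 0.3, 0), bbf_row = c(1, 0.5))
  expect_equal(bsinet_forward(model, pair), rep(1 / 32, 32),
               tolerance = 1e-12)
})

test_that("cross-entropy matches hand-computed values", {
  onehot <- function(i, C) { v <- numeric(C); v[i] <- 1; v }
  expect_equal(cross_entropy(onehot(2, 3), c(0, 1, 0)), 0)
  expect_equal(cross_entropy(onehot(1, 32), rep(1 / 32, 32)), log(32))
  expect_equal(cross_entropy(onehot(1, 2), c(0.5, 0.5)), log(2))
  expect_gte(cross_entropy(onehot(1, 4), c(0, 0.5, 0.25, 0.25)), 0)
  expect_true(is.finite(cross_entropy(onehot(1, 4), c(0, 0.5, 0.25, 0.25))))
})

test_that("one optimization step decreases the loss on a single example", {
  ds <- tiny_dataset()
  cfg <- config_for_dataset(ds, gat1_out = 4L, gat1_heads = 2L,
                            gat2_out = 4L, gat2_heads = 2L, fc_out = 8L,
                            mlp_hidden = c(16L, 8L), dropout = 0,
                            learning_rate = 1e-4)
  model <- bsinet_init(cfg, ds$d_atom, seed = 9L)
  idx <- 5L
  loss_at <- function(m) {
    fwd <- bsinet:::bsinet_batch_fwd(m, ds, idx)
    bsinet:::softmax_ce_fwd(fwd$mf$logits, ds$pairs$label0[idx])$loss
  }
  before <- loss_at(model)
  adam <- bsinet:::adam_state_init(model$params)
  step <- bsinet:::bsinet_batch_step(model, ds, idx, adam)
  expect_lt(loss_at(step$model), before)
})

test_that("checkpoints round-trip the model exactly", {
  model <- tiny_model()
  ds <- tiny_dataset()
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  model2 <- load_checkpoint(path)
  expect_equal(bsinet_predict(model2, ds, 1:10),
               bsinet_predict(model, ds, 1:10), tolerance = 1e-12)
})
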