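#' Network configuration
#'
#' Defaults realize the reference architecture: two graph attention
#' layers (4 heads of width 128, then 4 heads of width 256, concatenated),
#' layer normalization and feature dropout 0.2 between them, a per-node
#' fully connected layer to width 512 followed by mean pooling; the graph
#' vector is concatenated with the drug's fused similarity row (width
#' 2148 -> 2660), the biotech side concatenates the 1024-wide sequence
#' embedding with its 196-wide fused similarity row (-> 1220), and the
#' 3880-wide pair vector feeds a two-hidden-layer MLP ending in a softmax
#' over 32 interaction classes.
#'
#' @param gat1_out,gat1_heads first attention layer per-head width / heads.
#' @param gat2_out,gat2_heads second attention layer per-head width / heads.
#' @param dropout feature dropout rate between graph layers.
#' @param fc_out graph-branch output width.
#' @param ssf_width,bbf_width fused similarity row widths.
#' @param emb_width sequence embedding width.
#' @param n_classes number of interaction classes (negative class included).
#' @param mlp_hidden two hidden-layer widths of the classifier MLP.
#' @param learning_rate Adam learning rate.
#' @param epsilon training-loss threshold that stops an epoch loop.
#' @param max_epochs epoch budget per fold.
#' @param batch_size minibatch size.
#' @param negative_slope LeakyReLU slope in attention scores.
#' @param activation hidden nonlinearity of the graph layers.
#' @param normalization `"layer"` for per-node layer normalization between
#'   graph layers, `"none"` to disable.
#' @return object of class `bsinet_config`.
#' @export
#' @examples
#' cfg <- bsinet_config()
#' cfg$fc_out + cfg$ssf_width + cfg$emb_width + cfg$bbf_width  # 3880
bsinet_config <- function(gat1_out = 128L, gat1_heads = 4L,
                          gat2_out = 256L, gat2_heads = 4L,
                          dropout = 0.2, fc_out = 512L,
                          ssf_width = 2148L, bbf_width = 196L,
                          emb_width = 1024L, n_classes = 32L,
                          mlp_hidden = c(2048L, 512L),
                          learning_rate = 1e-3, epsilon = 0.05,
                          max_epochs = 10L, batch_size = 256L,
                          negative_slope = 0.2, activation = "elu",
                          normalization = c("layer", "none")) {
  check_that(n_classes >= 2, "need at least two classes")
  check_that(length(mlp_hidden) == 2, "mlp_hidden must give two widths")
  cfg <- list(
    gat1_out = as.integer(gat1_out), gat1_heads = as.integer(gat1_heads),
    gat2_out = as.integer(gat2_out), gat2_heads = as.integer(gat2_heads),
    dropout = dropout, fc_out = as.integer(fc_out),
    ssf_width = as.integer(ssf_width), bbf_width = as.integer(bbf_width),
    emb_width = as.integer(emb_width), n_classes = as.integer(n_classes),
    mlp_hidden = as.integer(mlp_hidden), learning_rate = learning_rate,
    epsilon = epsilon, max_epochs = as.integer(max_epochs),
    batch_size = as.integer(batch_size), negative_slope = negative_slope,
    activation = activation, normalization = match.arg(normalization)
  )
  cfg$pair_width <- cfg$fc_out + cfg$ssf_width + cfg$emb_width + cfg$bbf_width
  class(cfg) <- "bsinet_config"
  cfg
}

#' Initialize an untrained network
#'
#' @param cfg a [bsinet_config()].
#' @param d_atom atom feature width of the molecular graphs.
#' @param seed RNG seed for the parameter initialization.
#' @return object of class `bsinet_model` (config + parameter list).
#' @export
bsinet_init <- function(cfg = bsinet_config(), d_atom, seed = 1L) {
  with_rng(seed, {
    w1 <- cfg$gat1_out * cfg$gat1_heads
    w2 <- cfg$gat2_out * cfg$gat2_heads
    params <- list(
      gat1 = gat_params(d_atom, cfg$gat1_out, cfg$gat1_heads,
                        negative_slope = cfg$negative_slope,
                        activation = cfg$activation),
      ln1 = list(gamma = rep(1, w1), beta = rep(0, w1)),
      gat2 = gat_params(w1, cfg$gat2_out, cfg$gat2_heads,
                        negative_slope = cfg$negative_slope,
                        activation = cfg$activation),
      ln2 = list(gamma = rep(1, w2), beta = rep(0, w2)),
      fc = list(W = glorot(cfg$fc_out, w2), b = rep(0, cfg$fc_out)),
      mlp = list(
        W1 = he_init(cfg$mlp_hidden[1], cfg$pair_width),
        b1 = rep(0, cfg$mlp_hidden[1]),
        W2 = he_init(cfg$mlp_hidden[2], cfg$mlp_hidden[1]),
        b2 = rep(0, cfg$mlp_hidden[2]),
        W3 = he_init(cfg$n_classes, cfg$mlp_hidden[2]),
        b3 = rep(0, cfg$n_classes)
      )
    )
    structure(list(cfg = cfg, params = params, d_atom = as.integer(d_atom)),
              class = "bsinet_model")
  })
}

#' @export
print.bsinet_model <- function(x, ...) {
  cat(sprintf(paste0("<bsinet_model: d_atom=%d, GAT %dx%d -> %dx%d, ",
                     "fc_out=%d, pair=%d, classes=%d>\n"),
              x$d_atom, x$cfg$gat1_heads, x$cfg$gat1_out, x$cfg$gat2_heads,
              x$cfg$gat2_out, x$cfg$fc_out, x$cfg$pair_width, x$cfg$n_classes))
  invisible(x)
}

# --- batched graph branch -------------------------------------------------

#' Stack molecular graphs into one disconnected batch graph
#'
#' Node features are row-bound and edge indices offset, so one attention
#' pass covers every graph; mean pooling per graph id recovers per-graph
#' vectors.
#'
#' @param graphs list of `molecular_graph`s.
#' @return list with `H`, `edges`, `node_graph`, `graph_sizes`, `n_graphs`.
#' @export
build_graph_batch <- function(graphs) {
  check_that(length(graphs) > 0, "graph batch needs at least one graph")
  sizes <- vapply(graphs, `[[`, integer(1), "n_atoms")
  offsets <- cumsum(c(0L, sizes[-length(sizes)]))
  H <- do.call(rbind, lapply(graphs, `[[`, "node_features"))
  edges <- do.call(rbind, Map(function(g, off) g$edges + off,
                              graphs, offsets))
  list(H = H, edges = edges,
       node_graph = rep(seq_along(graphs), sizes),
       graph_sizes = sizes, n_graphs = length(graphs))
}

graph_branch_fwd <- function(batch, params, cfg, training = FALSE) {
  g1 <- gat_fwd(batch$H, batch$edges, params$gat1)
  if (cfg$normalization == "layer") {
    n1 <- layernorm_fwd(g1$Y, params$ln1$gamma, params$ln1$beta)
  } else {
    n1 <- list(Y = g1$Y)
  }
  d1 <- dropout_fwd(n1$Y, cfg$dropout, training)
  g2 <- gat_fwd(d1$Y, batch$edges, params$gat2)
  if (cfg$normalization == "layer") {
    n2 <- layernorm_fwd(g2$Y, params$ln2$gamma, params$ln2$beta)
  } else {
    n2 <- list(Y = g2$Y)
  }
  d2 <- dropout_fwd(n2$Y, cfg$dropout, training)
  fc <- linear_fwd(d2$Y, params$fc$W, params$fc$b)
  G <- rowsum(fc$Y, batch$node_graph) / batch$graph_sizes
  list(G = G, g1 = g1, n1 = n1, d1 = d1, g2 = g2, n2 = n2, d2 = d2, fc = fc)
}

graph_branch_bwd <- function(dG, cache, batch, params, cfg) {
  dFC <- (dG / batch$graph_sizes)[batch$node_graph, , drop = FALSE]
  lb <- linear_bwd(dFC, cache$fc, params$fc$W)
  d <- dropout_bwd(lb$dX, cache$d2)
  if (cfg$normalization == "layer") {
    ln2 <- layernorm_bwd(d, cache$n2, params$ln2$gamma)
    d <- ln2$dX
    g_ln2 <- list(gamma = ln2$dgamma, beta = ln2$dbeta)
  } else {
    g_ln2 <- list(gamma = params$ln2$gamma * 0, beta = params$ln2$beta * 0)
  }
  gb2 <- gat_bwd(d, cache$g2, params$gat2)
  d <- dropout_bwd(gb2$dH, cache$d1)
  if (cfg$normalization == "layer") {
    ln1 <- layernorm_bwd(d, cache$n1, params$ln1$gamma)
    d <- ln1$dX
    g_ln1 <- list(gamma = ln1$dgamma, beta = ln1$dbeta)
  } else {
    g_ln1 <- list(gamma = params$ln1$gamma * 0, beta = params$ln1$beta * 0)
  }
  gb1 <- gat_bwd(d, cache$g1, params$gat1)
  list(grads = list(gat1 = gb1$grads, ln1 = g_ln1, gat2 = gb2$grads,
                    ln2 = g_ln2, fc = list(W = lb$dW, b = lb$db)))
}

#' Graph branch: molecular graph to fixed-width drug vector
#'
#' Two multi-head attention layers (concatenated heads), each followed by
#' normalization and feature dropout, a per-node fully connected layer, and
#' mean pooling over atoms. Deterministic when `training` is FALSE.
#'
#' @param model a [bsinet_init()] model.
#' @param graph a `molecular_graph`.
#' @param training logical; activates dropout.
#' @return numeric vector of width `cfg$fc_out`.
#' @export
graph_branch <- function(model, graph, training = FALSE) {
  check_that(graph$n_atoms > 0, "graph branch: empty graph")
  batch <- build_graph_batch(list(graph))
  as.vector(graph_branch_fwd(batch, model$params, model$cfg, training)$G)
}

# --- feature concatenations ----------------------------------------------

#' Small-molecule pair-side vector: graph branch output then fused row
#' @param branch_out graph-branch vector (width fc_out).
#' @param ssf_row the drug's row of the fused small-molecule block.
#' @param cfg config used for width checking (optional).
#' @return numeric vector of width fc_out + ssf_width.
#' @export
small_molecule_vector <- function(branch_out, ssf_row, cfg = NULL) {
  if (!is.null(cfg)) {
    check_that(length(branch_out) == cfg$fc_out,
               "graph branch width %d != fc_out %d", length(branch_out),
               cfg$fc_out)
    check_that(length(ssf_row) == cfg$ssf_width,
               "SSf row width %d != ssf_width %d", length(ssf_row),
               cfg$ssf_width)
  }
  c(branch_out, ssf_row)
}

#' Biotech pair-side vector: sequence embedding then fused row
#' @param emb sequence embedding vector (width emb_width).
#' @param bbf_row the drug's row of the fused biotech block.
#' @param cfg config used for width checking (optional).
#' @return numeric vector of width emb_width + bbf_width.
#' @export
biotech_vector <- function(emb, bbf_row, cfg = NULL) {
  if (!is.null(cfg)) {
    check_that(length(emb) == cfg$emb_width,
               "embedding width %d != emb_width %d", length(emb),
               cfg$emb_width)
    check_that(length(bbf_row) == cfg$bbf_width,
               "BBf row width %d != bbf_width %d", length(bbf_row),
               cfg$bbf_width)
  }
  c(emb, bbf_row)
}

mlp_fwd <- function(X, mlp) {
  l1 <- linear_fwd(X, mlp$W1, mlp$b1)
  a1 <- relu_fwd(l1$Y)
  l2 <- linear_fwd(a1$Y, mlp$W2, mlp$b2)
  a2 <- relu_fwd(l2$Y)
  l3 <- linear_fwd(a2$Y, mlp$W3, mlp$b3)
  list(logits = l3$Y, l1 = l1, a1 = a1, l2 = l2, a2 = a2, l3 = l3)
}

mlp_bwd <- function(dlogits, cache, mlp) {
  l3 <- linear_bwd(dlogits, cache$l3, mlp$W3)
  d <- relu_bwd(l3$dX, cache$a2)
  l2 <- linear_bwd(d, cache$l2, mlp$W2)
  d <- relu_bwd(l2$dX, cache$a1)
  l1 <- linear_bwd(d, cache$l1, mlp$W1)
  list(dX = l1$dX,
       grads = list(W1 = l1$dW, b1 = l1$db, W2 = l2$dW, b2 = l2$db,
                    W3 = l3$dW, b3 = l3$db))
}

#' Forward pass for one drug pair
#'
#' Assembles `[graph branch || SSf row || embedding || BBf row]` and runs
#' the classifier MLP, returning the softmax class distribution.
#'
#' @param model a `bsinet_model`.
#' @param pair list with `graph` (`molecular_graph`), `ssf_row`, `emb`,
#'   `bbf_row`.
#' @param training logical; activates dropout.
#' @return probability vector of length `n_classes` (sums to 1).
#' @export
bsinet_forward <- function(model, pair, training = FALSE) {
  cfg <- model$cfg
  g <- graph_branch(model, pair$graph, training)
  x <- c(small_molecule_vector(g, pair$ssf_row, cfg),
         biotech_vector(pair$emb, pair$bbf_row, cfg))
  check_that(length(x) == cfg$pair_width, "pair vector width %d != %d",
             length(x), cfg$pair_width)
  out <- mlp_fwd(matrix(x, 1), model$params$mlp)
  as.vector(softmax_rows(out$logits))
}

#' Multiclass cross-entropy of a predicted distribution
#'
#' `-sum_i y_i log(p_i)` with probabilities clamped at 1e-12.
#'
#' @param y one-hot vector (or 0-based class index).
#' @param p probability vector.
#' @return non-negative scalar loss.
#' @export
#' @examples
#' cross_entropy(c(0, 1, 0), c(0.25, 0.5, 0.25))  # log(2)
cross_entropy <- function(y, p) {
  if (length(y) == 1) {
    yy <- numeric(length(p))
    yy[as.integer(y) + 1L] <- 1
    y <- yy
  }
  check_that(length(y) == length(p), "cross_entropy: length mismatch")
  -sum(y * log(pmax(p, 1e-12)))
}

# --- batched training-time forward/backward over an assembled dataset ----

# dataset: list(graph_batch, SSf, EMB, BBf, pairs(sm_idx, bt_idx, label0))
bsinet_batch_fwd <- function(model, dataset, idx, training = FALSE) {
  cfg <- model$cfg
  gb <- graph_branch_fwd(dataset$graph_batch, model$params, cfg, training)
  sm <- dataset$pairs$sm_idx[idx]
  bt <- dataset$pairs$bt_idx[idx]
  X <- cbind(gb$G[sm, , drop = FALSE],
             dataset$SSf[sm, , drop = FALSE],
             dataset$EMB[bt, , drop = FALSE],
             dataset$BBf[bt, , drop = FALSE])
  mf <- mlp_fwd(X, model$params$mlp)
  list(gb = gb, mf = mf, sm = sm, bt = bt,
       probs = softmax_rows(mf$logits))
}

bsinet_batch_step <- function(model, dataset, idx, adam) {
  fwd <- bsinet_batch_fwd(model, dataset, idx, training = TRUE)
  y <- dataset$pairs$label0[idx]
  ce <- softmax_ce_fwd(fwd$mf$logits, y)
  mb <- mlp_bwd(ce$dlogits, fwd$mf, model$params$mlp)
  dG_rows <- mb$dX[, seq_len(model$cfg$fc_out), drop = FALSE]
  dG <- scatter_add(dG_rows, fwd$sm, dataset$graph_batch$n_graphs)
  gb <- graph_branch_bwd(dG, fwd$gb, dataset$graph_batch, model$params,
                         model$cfg)
  grads <- c(gb$grads, list(mlp = mb$grads))
  upd <- adam_step(model$params[names(grads)], grads, adam,
                   model$cfg$learning_rate)
  model$params[names(grads)] <- upd$params
  list(model = model, adam = upd$state, loss = ce$loss)
}

#' Predict class probabilities for pair indices of an assembled dataset
#'
#' @param model a trained `bsinet_model`.
#' @param dataset an [assemble_dataset()] result.
#' @param idx pair row indices to score (default: all pairs).
#' @return probability matrix (length(idx) x n_classes).
#' @export
bsinet_predict <- function(model, dataset, idx = seq_len(nrow(dataset$pairs))) {
  fwd <- bsinet_batch_fwd(model, dataset, idx, training = FALSE)
  dimnames(fwd$probs) <- list(NULL, dataset$class_names %||% NULL)
  fwd$probs
}
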