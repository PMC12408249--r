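# Dataset assembly, stratified folds, the epoch training loop, and
# cross-validated evaluation shared by the attention model and baselines.

#' Build every feature block of a corpus and assemble the pair dataset
#'
#' Computes, from the raw corpus: molecular graphs and circular
#' fingerprints for the small molecules; the SSI/SSs/SST and BBI/BBs/BBT
#' interaction and similarity matrices; their fused sums SSf and BBf; and
#' the per-drug sequence embeddings (multi-chain drugs averaged). Pair rows
#' are indexed against the drug rosters so every classifier consumes the
#' same assembled blocks.
#'
#' @param corpus a corpus list as produced by [generate_corpus()] or
#'   [load_corpus()].
#' @param embedder a `sequence_embedder` (default [stub_embedder()]).
#' @param fp_radius,fp_bits circular fingerprint parameters.
#' @param featurizer atom featurizer configuration.
#' @return a dataset list with `graphs`, `graph_batch`, `SSf`, `BBf`,
#'   `EMB`, `pairs` (sm_idx, bt_idx, label0), `class_names`, `blocks`
#'   (all six component matrices), `d_atom`.
#' @export
assemble_dataset <- function(corpus, embedder = stub_embedder(),
                             fp_radius = 2L, fp_bits = 2048L,
                             featurizer = atom_featurizer_config()) {
  sm_ids <- names(corpus$smiles)
  bt_ids <- vapply(corpus$proteins, `[[`, character(1), "drug_id")
  graphs <- lapply(seq_along(corpus$smiles), function(i) {
    smiles_to_graph(corpus$smiles[[i]], featurizer, drug_id = sm_ids[i])
  })
  fps <- lapply(graphs, morgan_fingerprint, radius = fp_radius,
                n_bits = fp_bits)
  names(fps) <- sm_ids
  SSs <- tanimoto_similarity(fps)
  SSI <- interaction_matrix(corpus$ssi_edges, sm_ids, symmetric = TRUE)
  STI <- interaction_matrix(corpus$sti_edges, sm_ids, corpus$sm_targets)
  SST <- interaction_cosine(STI)
  SSf <- fuse_feature_block(SSI, SST, SSs)

  seqs <- vapply(corpus$proteins, function(p) paste(p$chains, collapse = ""),
                 character(1))
  names(seqs) <- bt_ids
  BBs <- global_alignment_similarity(seqs)
  BBI <- interaction_matrix(corpus$bbi_edges, bt_ids, symmetric = TRUE)
  BTI <- interaction_matrix(corpus$bti_edges, bt_ids, corpus$bt_targets)
  BBT <- interaction_cosine(BTI)
  BBf <- fuse_feature_block(BBI, BBT, BBs)
  EMB <- embed_records(corpus$proteins, embedder)

  vocab <- corpus$label_vocab
  sm_idx <- match(corpus$pairs$sm_id, sm_ids)
  bt_idx <- match(corpus$pairs$bt_id, bt_ids)
  label0 <- match(corpus$pairs$label, vocab) - 1L
  check_that(!anyNA(sm_idx) && !anyNA(bt_idx),
             "pairs reference drugs missing from the rosters")
  check_that(!anyNA(label0), "pairs carry labels missing from the vocabulary")
  list(
    graphs = graphs, graph_batch = build_graph_batch(graphs),
    SSf = SSf, BBf = BBf, EMB = EMB,
    pairs = data.frame(sm_id = corpus$pairs$sm_id,
                       bt_id = corpus$pairs$bt_id,
                       sm_idx = sm_idx, bt_idx = bt_idx, label0 = label0,
                       stringsAsFactors = FALSE),
    class_names = vocab, d_atom = featurizer$d_atom,
    blocks = list(SSI = SSI, SSs = SSs, SST = SST, STI = STI,
                  BBI = BBI, BBs = BBs, BBT = BBT, BTI = BTI),
    n_small = length(sm_ids), n_biotech = length(bt_ids)
  )
}

#' Network configuration matched to an assembled dataset
#'
#' Fills the similarity-row, embedding and class-count widths from the
#' dataset; all other fields keep their [bsinet_config()] defaults unless
#' overridden through `...`.
#'
#' @param dataset an [assemble_dataset()] result.
#' @param ... overrides forwarded to [bsinet_config()].
#' @return a `bsinet_config`.
#' @export
config_for_dataset <- function(dataset, ...) {
  args <- list(...)
  args$ssf_width <- ncol(dataset$SSf)
  args$bbf_width <- ncol(dataset$BBf)
  args$emb_width <- ncol(dataset$EMB)
  args$n_classes <- length(dataset$class_names)
  do.call(bsinet_config, args)
}

#' Stratified k-fold assignment
#'
#' Shuffles within each class (deterministically from `seed`) and deals
#' examples round-robin, so per-fold class counts differ from exact
#' proportionality by at most one example per class. Rotating the dealing
#' start across classes balances total fold sizes.
#'
#' @param labels class labels (any atomic type).
#' @param k fold count.
#' @param seed RNG seed.
#' @return object of class `fold_plan`: `k`, `assignments` (1..k per
#'   example), `seed`.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  k <- as.integer(k)
  check_that(k >= 2, "need at least two folds")
  counts <- table(labels)
  small <- names(counts)[counts < k]
  if (length(small) > 0) {
    abort("class(es) with fewer than k=%d examples: %s", k,
          paste(small, collapse = ", "))
  }
  assignments <- integer(length(labels))
  offset <- 0L
  with_rng(seed, {
    for (cl in names(counts)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      assignments[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- offset + length(idx) %% k
    }
  })
  structure(list(k = k, assignments = assignments, seed = as.integer(seed)),
            class = "fold_plan")
}

#' Train the network on one training split
#'
#' Runs minibatch Adam epochs over the training pairs, shuffled per epoch,
#' and stops as soon as the epoch mean training loss drops below
#' `cfg$epsilon` or the epoch budget is exhausted.
#'
#' @param model an initialized `bsinet_model`.
#' @param dataset an [assemble_dataset()] result.
#' @param train_idx pair row indices to train on.
#' @param seed RNG seed for shuffling and dropout.
#' @param verbose print per-epoch losses.
#' @return list with the trained `model` and `trace`
#'   (data.frame epoch/loss).
#' @export
train_fold <- function(model, dataset, train_idx, seed = 1L,
                       verbose = FALSE) {
  check_that(length(train_idx) > 0, "empty training set")
  cfg <- model$cfg
  adam <- adam_state_init(model$params)
  trace <- data.frame(epoch = integer(0), loss = numeric(0))
  with_rng(seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      order_idx <- train_idx[sample.int(length(train_idx))]
      starts <- seq(1, length(order_idx), by = cfg$batch_size)
      losses <- numeric(length(starts))
      for (b in seq_along(starts)) {
        take <- order_idx[starts[b]:min(starts[b] + cfg$batch_size - 1L,
                                        length(order_idx))]
        step <- bsinet_batch_step(model, dataset, take, adam)
        if (!is.finite(step$loss)) {
          abort("non-finite training loss at epoch %d batch %d", epoch, b)
        }
        model <- step$model
        adam <- step$adam
        losses[b] <- step$loss
      }
      epoch_loss <- mean(losses)
      trace <- rbind(trace, data.frame(epoch = epoch, loss = epoch_loss))
      if (verbose) message(sprintf("epoch %d loss %.4f", epoch, epoch_loss))
      if (epoch_loss < cfg$epsilon) break
    }
  })
  list(model = model, trace = trace)
}

.fold_metrics_row <- function(rep, fold) {
  do.call(rbind, lapply(c("micro", "macro", "weighted"), function(r) {
    m <- rep[[r]]
    data.frame(fold = fold, regime = r, precision = m$precision,
               recall = m$recall, f1 = m$f1, accuracy = m$accuracy,
               mcc = m$mcc %||% NA_real_, auroc = m$auroc, aupr = m$aupr)
  }))
}

#' Stratified cross-validated training and evaluation
#'
#' For each fold: train on the remaining folds, score the held-out fold.
#' Out-of-fold predictions are pooled and scored once, and per-fold
#' metrics are summarized as mean and standard deviation across folds.
#' The attention network and every baseline consume the identical fold
#' plan and are scored by the same [metrics_report()] code path.
#'
#' @param dataset an [assemble_dataset()] result.
#' @param cfg a `bsinet_config` (used for `model = "bsinet"`); defaults to
#'   [config_for_dataset()].
#' @param k fold count (default 10).
#' @param seed seed controlling folds, initialization, shuffling, dropout.
#' @param model `"bsinet"` or a baseline kind
#'   (`"svm"`, `"random_forest"`, `"xgboost"`, `"mlp3"`, `"cnn3"`).
#' @param baseline_spec optional [baseline_spec()] overriding `model`.
#' @param verbose print progress.
#' @return list: `pooled` ([metrics_report()]), `per_fold` (data.frame),
#'   `fold_summary` (mean/sd per regime and metric), `predictions`,
#'   `prob_matrix`, `fold_plan`, `loss_traces`, `model_kind`.
#' @export
run_cv <- function(dataset, cfg = NULL, k = 10L, seed = 1L,
                   model = "bsinet", baseline_spec = NULL,
                   verbose = FALSE) {
  labels <- dataset$pairs$label0
  n <- length(labels)
  n_classes <- length(dataset$class_names)
  plan <- stratified_folds(labels, k, seed)
  prob <- matrix(NA_real_, n, n_classes)
  traces <- list()
  per_fold <- list()
  if (!is.null(baseline_spec)) model <- baseline_spec$kind
  is_net <- identical(model, "bsinet")
  if (is_net && is.null(cfg)) cfg <- config_for_dataset(dataset)
  X <- if (!is_net) baseline_feature_matrix(dataset) else NULL
  for (fold in seq_len(plan$k)) {
    test_idx <- which(plan$assignments == fold)
    train_idx <- which(plan$assignments != fold)
    fold_seed <- derive_seed(seed, fold)
    if (is_net) {
      net <- bsinet_init(cfg, dataset$d_atom, seed = fold_seed)
      fit <- train_fold(net, dataset, train_idx, seed = fold_seed,
                        verbose = verbose)
      traces[[fold]] <- transform(fit$trace, fold = fold)
      prob[test_idx, ] <- bsinet_predict(fit$model, dataset, test_idx)
    } else {
      spec <- baseline_spec %||% baseline_spec_default(model,
                                                       seed = fold_seed)
      spec$seed <- fold_seed
      bl <- fit_baseline(spec, X[train_idx, , drop = FALSE],
                         labels[train_idx], n_classes = n_classes)
      prob[test_idx, ] <- predict_baseline(bl, X[test_idx, , drop = FALSE])$prob
    }
    y_hat_fold <- max.col(prob[test_idx, , drop = FALSE]) - 1L
    rep_fold <- suppressWarnings(
      metrics_report(labels[test_idx], y_hat_fold,
                     prob[test_idx, , drop = FALSE], n_classes)
    )
    per_fold[[fold]] <- .fold_metrics_row(rep_fold, fold)
    if (verbose) message(sprintf("fold %d/%d done", fold, plan$k))
  }
  y_hat <- max.col(prob) - 1L
  pooled <- metrics_report(labels, y_hat, prob, n_classes)
  pf <- do.call(rbind, per_fold)
  metric_cols <- c("precision", "recall", "f1", "accuracy", "mcc",
                   "auroc", "aupr")
  fold_summary <- do.call(rbind, lapply(split(pf, pf$regime), function(d) {
    data.frame(regime = d$regime[1], metric = metric_cols,
               mean = vapply(metric_cols, function(m) mean(d[[m]]),
                             numeric(1)),
               sd = vapply(metric_cols, function(m) stats::sd(d[[m]]),
                           numeric(1)),
               row.names = NULL)
  }))
  list(
    pooled = pooled, per_fold = pf, fold_summary = fold_summary,
    predictions = data.frame(dataset$pairs,
                             predicted = dataset$class_names[y_hat + 1L],
                             stringsAsFactors = FALSE),
    prob_matrix = prob, fold_plan = plan,
    loss_traces = if (length(traces)) do.call(rbind, traces) else NULL,
    model_kind = model
  )
}
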