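# Comparator models operating on concatenated similarity rows.

#' Pair feature row for the similarity-only baselines
#'
#' Concatenates the small molecule's fused similarity row with the biotech
#' drug's fused similarity row (SSf row first). At the reference corpus
#' scale the result has width 2148 + 196 = 2344.
#'
#' @param i small-molecule row index (1-based).
#' @param j biotech row index (1-based).
#' @param SSf,BBf fused feature blocks.
#' @return numeric vector of width `ncol(SSf) + ncol(BBf)`.
#' @export
pair_row_features <- function(i, j, SSf, BBf) {
  check_that(i >= 1 && i <= nrow(SSf), "small-molecule index %d out of range", i)
  check_that(j >= 1 && j <= nrow(BBf), "biotech index %d out of range", j)
  c(SSf[i, ], BBf[j, ])
}

#' Baseline feature matrix for every pair of an assembled dataset
#' @param dataset an [assemble_dataset()] result.
#' @param idx pair rows to build (default all).
#' @return numeric matrix, one [pair_row_features()] row per pair.
#' @export
baseline_feature_matrix <- function(dataset,
                                    idx = seq_len(nrow(dataset$pairs))) {
  X <- cbind(dataset$SSf[dataset$pairs$sm_idx[idx], , drop = FALSE],
             dataset$BBf[dataset$pairs$bt_idx[idx], , drop = FALSE])
  rownames(X) <- NULL
  colnames(X) <- c(paste0("ssf", seq_len(ncol(dataset$SSf))),
                   paste0("bbf", seq_len(ncol(dataset$BBf))))
  X
}

#' Specification of a comparator model
#'
#' @param kind one of `"svm"`, `"random_forest"`, `"xgboost"`, `"mlp3"`,
#'   `"cnn3"`.
#' @param hyperparameters named list of overrides (recorded verbatim on the
#'   fitted model).
#' @param seed RNG seed for reproducibility.
#' @return object of class `baseline_spec`.
#' @export
baseline_spec <- function(kind = c("svm", "random_forest", "xgboost",
                                   "mlp3", "cnn3"),
                          hyperparameters = list(), seed = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, hyperparameters = hyperparameters,
                 seed = as.integer(seed)),
            class = "baseline_spec")
}

baseline_spec_default <- function(kind, seed = 1L) {
  baseline_spec(kind, seed = seed)
}

#' Fit a comparator model
#'
#' All baselines expose class-probability predictions so the shared
#' metrics pipeline (including one-vs-rest AUROC/AUPR) can score them.
#' SVM probabilities come from e1071's cross-validated sigmoid calibration
#' of the one-vs-one decision values; the random forest is a ranger
#' probability forest; XGBoost uses the multiclass softprob objective. The
#' three-layer MLP and the 1-D CNN (three conv + batch-norm + dropout
#' blocks, then a dense softmax layer) are trained with Adam on the
#' package's own layer primitives.
#'
#' @param spec a [baseline_spec()].
#' @param X feature matrix (rows = examples).
#' @param y 0-based integer class labels.
#' @param n_classes total class count (default: `max(y) + 1`).
#' @return object of class `baseline_model`.
#' @export
fit_baseline <- function(spec, X, y, n_classes = NULL) {
  y <- as.integer(y)
  n_classes <- as.integer(n_classes %||% (max(y) + 1L))
  check_that(length(unique(y)) >= 2,
             "baseline training needs at least two classes in y")
  check_that(nrow(X) == length(y), "X rows must match y length")
  hp <- spec$hyperparameters
  seen <- sort(unique(y))
  fit <- with_rng(spec$seed, switch(spec$kind,
    svm = e1071::svm(
      x = X, y = factor(y, levels = seen), probability = TRUE,
      kernel = hp$kernel %||% "radial", cost = hp$cost %||% 1,
      scale = FALSE
    ),
    random_forest = ranger::ranger(
      x = X, y = factor(y, levels = seen), probability = TRUE,
      num.trees = hp$num_trees %||% 500,
      mtry = hp$mtry %||% floor(sqrt(ncol(X))),
      seed = spec$seed, num.threads = 1
    ),
    xgboost = {
      dtrain <- xgboost::xgb.DMatrix(data = X,
                                     label = match(y, seen) - 1L)
      xgboost::xgb.train(
        params = list(objective = "multi:softprob",
                      num_class = length(seen),
                      max_depth = hp$max_depth %||% 6,
                      eta = hp$eta %||% 0.3,
                      nthread = 1, seed = spec$seed),
        data = dtrain, nrounds = hp$nrounds %||% 100, verbose = 0
      )
    },
    mlp3 = .fit_mlp3(X, match(y, seen) - 1L, length(seen), hp, spec$seed),
    cnn3 = .fit_cnn3(X, match(y, seen) - 1L, length(seen), hp, spec$seed)
  ))
  structure(list(kind = spec$kind, fit = fit, seen = seen,
                 n_classes = n_classes, hyperparameters = hp,
                 seed = spec$seed),
            class = "baseline_model")
}

#' Predict classes and class probabilities from a fitted comparator
#'
#' @param model a [fit_baseline()] result.
#' @param X feature matrix.
#' @return list with `class` (0-based integer predictions) and `prob`
#'   (matrix, one column per class 0..n_classes-1).
#' @export
predict_baseline <- function(model, X) {
  seen <- model$seen
  raw <- switch(model$kind,
    svm = {
      p <- stats::predict(model$fit, X, probability = TRUE)
      pr <- attr(p, "probabilities")
      pr[, match(as.character(seen), colnames(pr)), drop = FALSE]
    },
    random_forest = {
      pr <- stats::predict(model$fit, data = X,
                           num.threads = 1)$predictions
      pr[, match(as.character(seen), colnames(pr)), drop = FALSE]
    },
    xgboost = {
      p <- stats::predict(model$fit, xgboost::xgb.DMatrix(data = X))
      if (is.matrix(p)) p else matrix(p, nrow(X), length(seen),
                                      byrow = TRUE)
    },
    mlp3 = .predict_net(model$fit, X),
    cnn3 = .predict_net(model$fit, X)
  )
  prob <- matrix(0, nrow(X), model$n_classes)
  prob[, seen + 1L] <- raw
  cls <- max.col(prob) - 1L
  list(class = cls, prob = prob)
}

# --- three-layer MLP comparator ------------------------------------------

.fit_mlp3 <- function(X, y, C, hp, seed) {
  hidden <- hp$hidden %||% c(256L, 128L)
  lr <- hp$learning_rate %||% 1e-3
  epochs <- hp$epochs %||% 30L
  batch <- hp$batch_size %||% 128L
  params <- list(W1 = he_init(hidden[1], ncol(X)), b1 = rep(0, hidden[1]),
                 W2 = he_init(hidden[2], hidden[1]), b2 = rep(0, hidden[2]),
                 W3 = he_init(C, hidden[2]), b3 = rep(0, C))
  adam <- adam_state_init(params)
  n <- nrow(X)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (s in seq(1, n, by = batch)) {
      take <- ord[s:min(s + batch - 1L, n)]
      fwd <- mlp_fwd(X[take, , drop = FALSE], params)
      ce <- softmax_ce_fwd(fwd$logits, y[take])
      bw <- mlp_bwd(ce$dlogits, fwd, params)
      upd <- adam_step(params, bw$grads, adam, lr)
      params <- upd$params
      adam <- upd$state
    }
  }
  list(type = "mlp3", params = params)
}

# --- 1-D CNN comparator ---------------------------------------------------

# im2col index map for a 1-D convolution with zero padding
.conv_index <- function(L, k, stride, pad) {
  out_len <- (L + 2L * pad - k) %/% stride + 1L
  pos <- outer((seq_len(out_len) - 1L) * stride - pad, seq_len(k), `+`)
  pos[pos < 1 | pos > L] <- NA_integer_   # zero-padded taps
  list(pos = pos, out_len = out_len)
}

.conv1d_fwd <- function(A, W, b, idx) {
  # A: n x L x C_in array; W: C_out x (k*C_in); returns n x out_len x C_out.
  # im2col row r = (t-1)*n + i holds the window of sample i at position t.
  n <- dim(A)[1]; C_in <- dim(A)[3]
  k <- ncol(idx$pos)
  M <- matrix(0, n * idx$out_len, k * C_in)
  for (u in seq_len(k)) {
    p <- idx$pos[, u]
    ok <- which(!is.na(p))
    if (length(ok) == 0) next
    rows <- as.vector(outer(seq_len(n), (ok - 1L) * n, `+`))
    M[rows, (u - 1L) * C_in + seq_len(C_in)] <-
      matrix(A[, p[ok], , drop = FALSE], n * length(ok), C_in)
  }
  Y <- sweep(M %*% t(W), 2, b, `+`)
  list(Y = array(Y, c(n, idx$out_len, nrow(W))), M = M, n = n)
}

.conv1d_bwd <- function(dY, cache, W, idx, L, C_in) {
  n <- cache$n
  k <- ncol(idx$pos)
  dYm <- matrix(dY, n * idx$out_len, dim(dY)[3])
  dW <- t(dYm) %*% cache$M
  db <- colSums(dYm)
  dM <- dYm %*% W
  dA <- array(0, c(n, L, C_in))
  for (u in seq_len(k)) {
    p <- idx$pos[, u]
    ok <- which(!is.na(p))
    for (t in ok) {   # source positions overlap across t: scatter-add
      dA[, p[t], ] <- dA[, p[t], ] +
        dM[(t - 1L) * n + seq_len(n), (u - 1L) * C_in + seq_len(C_in)]
    }
  }
  list(dA = dA, dW = dW, db = db)
}

.bn_fwd <- function(Y, gamma, beta, training, run, momentum = 0.9,
                    eps = 1e-5) {
  # Y: n x L x C; normalize per channel over batch and positions
  d <- dim(Y)
  Ym <- matrix(Y, d[1] * d[2], d[3])
  if (training) {
    mu <- colMeans(Ym)
    v <- colMeans(Ym^2) - mu^2
    run$mean <- momentum * run$mean + (1 - momentum) * mu
    run$var <- momentum * run$var + (1 - momentum) * v
  } else {
    mu <- run$mean
    v <- run$var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(Ym, 2, mu), 2, inv, `*`)
  out <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(Y = array(out, d), xhat = xhat, inv = inv, dims = d, run = run)
}

.bn_bwd <- function(dY, cache, gamma) {
  d <- cache$dims
  dYm <- matrix(dY, d[1] * d[2], d[3])
  m <- nrow(dYm)
  dgamma <- colSums(dYm * cache$xhat)
  dbeta <- colSums(dYm)
  dxhat <- sweep(dYm, 2, gamma, `*`)
  dX <- sweep(dxhat - matrix(colMeans(dxhat), m, d[3], byrow = TRUE) -
                cache$xhat * matrix(colMeans(dxhat * cache$xhat), m, d[3],
                                    byrow = TRUE),
              2, cache$inv, `*`)
  list(dX = array(dX, d), dgamma = dgamma, dbeta = dbeta)
}

.cnn_arch <- function(L, C, hp) {
  channels <- hp$channels %||% c(16L, 32L, 64L)
  k <- hp$kernel %||% 7L
  stride <- hp$stride %||% 2L
  pad <- k %/% 2L
  idx <- list()
  len <- L
  c_in <- 1L
  for (b in 1:3) {
    idx[[b]] <- .conv_index(len, k, stride, pad)
    len <- idx[[b]]$out_len
    c_in <- channels[b]
  }
  list(channels = channels, k = k, stride = stride, pad = pad, idx = idx,
       flat = len * channels[3], dropout = hp$dropout %||% 0.2)
}

.cnn_init <- function(L, C, hp) {
  arch <- .cnn_arch(L, C, hp)
  ch <- c(1L, arch$channels)
  params <- list()
  for (b in 1:3) {
    params[[paste0("W", b)]] <- he_init(ch[b + 1L], arch$k * ch[b])
    params[[paste0("b", b)]] <- rep(0, ch[b + 1L])
    params[[paste0("g", b)]] <- rep(1, ch[b + 1L])
    params[[paste0("be", b)]] <- rep(0, ch[b + 1L])
  }
  params$Wd <- he_init(C, arch$flat)
  params$bd <- rep(0, C)
  run <- lapply(1:3, function(b) list(mean = rep(0, ch[b + 1L]),
                                      var = rep(1, ch[b + 1L])))
  list(arch = arch, params = params, run = run)
}

.cnn_fwd <- function(net, X, training) {
  arch <- net$arch
  A <- array(X, c(nrow(X), ncol(X), 1L))
  caches <- list()
  for (b in 1:3) {
    cv <- .conv1d_fwd(A, net$params[[paste0("W", b)]],
                      net$params[[paste0("b", b)]], arch$idx[[b]])
    bn <- .bn_fwd(cv$Y, net$params[[paste0("g", b)]],
                  net$params[[paste0("be", b)]], training, net$run[[b]])
    net$run[[b]] <- bn$run
    ac <- relu_fwd(bn$Y)
    dp <- dropout_fwd(matrix(ac$Y, nrow(X)), arch$dropout, training)
    A_next <- array(dp$Y, dim(bn$Y))
    caches[[b]] <- list(cv = cv, bn = bn, ac = ac, dp = dp,
                        in_len = dim(A)[2], in_ch = dim(A)[3])
    A <- A_next
  }
  flat <- matrix(A, nrow(X), arch$flat)
  dense <- linear_fwd(flat, net$params$Wd, net$params$bd)
  list(logits = dense$Y, dense = dense, flat_dims = dim(A),
       caches = caches, net = net)
}

.cnn_bwd <- function(dlogits, fw, net) {
  arch <- net$arch
  grads <- list()
  lb <- linear_bwd(dlogits, fw$dense, net$params$Wd)
  grads$Wd <- lb$dW
  grads$bd <- lb$db
  dA <- array(lb$dX, fw$flat_dims)
  for (b in 3:1) {
    cc <- fw$caches[[b]]
    d <- dropout_bwd(matrix(dA, dim(dA)[1]), cc$dp)
    d <- array(d, dim(dA)) * (cc$ac$X > 0)
    bn <- .bn_bwd(d, cc$bn, net$params[[paste0("g", b)]])
    grads[[paste0("g", b)]] <- bn$dgamma
    grads[[paste0("be", b)]] <- bn$dbeta
    cv <- .conv1d_bwd(bn$dX, cc$cv, net$params[[paste0("W", b)]],
                      arch$idx[[b]], cc$in_len, cc$in_ch)
    grads[[paste0("W", b)]] <- cv$dW
    grads[[paste0("b", b)]] <- cv$db
    dA <- cv$dA
  }
  grads
}

.fit_cnn3 <- function(X, y, C, hp, seed) {
  lr <- hp$learning_rate %||% 1e-3
  epochs <- hp$epochs %||% 20L
  batch <- hp$batch_size %||% 128L
  net <- .cnn_init(ncol(X), C, hp)
  adam <- adam_state_init(net$params)
  n <- nrow(X)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (s in seq(1, n, by = batch)) {
      take <- ord[s:min(s + batch - 1L, n)]
      fw <- .cnn_fwd(net, X[take, , drop = FALSE], training = TRUE)
      net <- fw$net
      ce <- softmax_ce_fwd(fw$logits, y[take])
      grads <- .cnn_bwd(ce$dlogits, fw, net)
      upd <- adam_step(net$params[names(grads)], grads, adam, lr)
      net$params[names(grads)] <- upd$params
      adam <- upd$state
    }
  }
  list(type = "cnn3", net = net)
}

.predict_net <- function(fit, X) {
  if (fit$type == "mlp3") {
    softmax_rows(mlp_fwd(X, fit$params)$logits)
  } else {
    softmax_rows(.cnn_fwd(fit$net, X, training = FALSE)$logits)
  }
}
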