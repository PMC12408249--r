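# Minimal dense neural-network primitives with manual backpropagation.
# All layers are pure functions: *_fwd returns the output plus the cache its
# *_bwd needs; gradients are exact, which the test suite verifies against
# central finite differences.

linear_fwd <- function(X, W, b) {
  # X: n x d_in, W: d_out x d_in, b: d_out
  Y <- X %*% t(W)
  Y <- sweep(Y, 2, b, `+`)
  list(Y = Y, X = X)
}

linear_bwd <- function(dY, cache, W) {
  list(dX = dY %*% W, dW = t(dY) %*% cache$X, db = colSums(dY))
}

relu_fwd <- function(X) list(Y = pmax(X, 0), X = X)
relu_bwd <- function(dY, cache) dY * (cache$X > 0)

elu_fwd <- function(X) {
  Y <- ifelse(X > 0, X, exp(pmin(X, 0)) - 1)
  list(Y = Y, X = X)
}
elu_bwd <- function(dY, cache) {
  dY * ifelse(cache$X > 0, 1, exp(pmin(cache$X, 0)))
}

identity_fwd <- function(X) list(Y = X)
identity_bwd <- function(dY, cache) dY

act_fwd <- function(X, kind) {
  switch(kind, elu = elu_fwd(X), relu = relu_fwd(X), identity = identity_fwd(X),
         abort("unknown activation '%s'", kind))
}
act_bwd <- function(dY, cache, kind) {
  switch(kind, elu = elu_bwd(dY, cache), relu = relu_bwd(dY, cache),
         identity = identity_bwd(dY, cache))
}

# Per-row (per-node) layer normalization with learned scale/shift.
layernorm_fwd <- function(X, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  Y <- sweep(xhat, 2, gamma, `*`)
  Y <- sweep(Y, 2, beta, `+`)
  list(Y = Y, xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dY, cache, gamma) {
  xhat <- cache$xhat
  dxhat <- sweep(dY, 2, gamma, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dX = dX, dgamma = colSums(dY * xhat), dbeta = colSums(dY))
}

# Inverted dropout: scaling at train time, identity at eval time.
dropout_fwd <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(Y = X, mask = NULL))
  mask <- matrix(stats::rbinom(length(X), 1, 1 - rate) / (1 - rate),
                 nrow(X), ncol(X))
  list(Y = X * mask, mask = mask)
}
dropout_bwd <- function(dY, cache) {
  if (is.null(cache$mask)) dY else dY * cache$mask
}

# Row-wise softmax with max subtraction.
softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Mean cross-entropy of probabilities P (n x C) against 0-based labels y,
# with probability clamping; returns loss and the gradient w.r.t. logits.
softmax_ce_fwd <- function(logits, y) {
  P <- softmax_rows(logits)
  n <- nrow(P)
  p_true <- pmax(P[cbind(seq_len(n), y + 1L)], 1e-12)
  loss <- -mean(log(p_true))
  Yhot <- matrix(0, n, ncol(P))
  Yhot[cbind(seq_len(n), y + 1L)] <- 1
  list(loss = loss, P = P, dlogits = (P - Yhot) / n)
}

glorot <- function(n_out, n_in) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_out * n_in, -lim, lim), n_out, n_in)
}

he_init <- function(n_out, n_in) {
  matrix(stats::rnorm(n_out * n_in, 0, sqrt(2 / n_in)), n_out, n_in)
}

# --- Adam over an arbitrarily nested list of numeric arrays ---------------

# The walk is driven by the gradient structure, so non-numeric metadata
# fields living alongside parameters (head counts, combine modes) are
# silently carried through untouched. Moment slots are created lazily.
adam_state_init <- function(params) list(mom = list(), t = 0L)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  t <- state$t + 1L
  walk <- function(p, g, s) {
    if (is.list(g)) {
      if (is.null(s)) s <- stats::setNames(vector("list", length(g)),
                                           names(g))
      for (nm in names(g)) {
        r <- walk(p[[nm]], g[[nm]], s[[nm]])
        p[[nm]] <- r$p
        s[[nm]] <- r$s
      }
      return(list(p = p, s = s))
    }
    if (is.null(s)) s <- list(m = g * 0, v = g * 0)
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mhat <- s$m / (1 - beta1^t)
    vhat <- s$v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), s = s)
  }
  r <- walk(params, grads, state$mom)
  list(params = r$p, state = list(mom = r$s, t = t))
}
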