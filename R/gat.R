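# Multi-head graph attention layer.
#
# Per head k with weight matrix W and attention vector a, the layer
# computes for every directed edge (i <- j), j in N(i):
#   e_ij    = LeakyReLU(a^T [W h_i || W h_j])
#   alpha_ij = softmax_{j in N(i)}(e_ij)
#   h'_i    = sigma(sum_j alpha_ij W h_j)
# and combines heads by concatenation (width K * d_out) or averaging
# (width d_out). Self-loops in the edge list keep every N(i) non-empty.

#' Initialize multi-head graph attention layer parameters
#'
#' @param d_in input node-feature width.
#' @param d_out per-head output width.
#' @param heads number of attention heads K (>= 1).
#' @param combine head combination, `"concat"` (layer width K * d_out) or
#'   `"average"` (width d_out).
#' @param negative_slope LeakyReLU slope for attention scores.
#' @param activation per-head output nonlinearity (`"elu"`, `"relu"`,
#'   `"identity"`).
#' @return object of class `gat_params`: per-head `W` (d_out x d_in) and
#'   `a` (2 * d_out), plus the layer hyperparameters.
#' @export
gat_params <- function(d_in, d_out, heads = 4L, combine = c("concat", "average"),
                       negative_slope = 0.2, activation = "elu") {
  combine <- match.arg(combine)
  check_that(heads >= 1, "need at least one attention head")
  hs <- lapply(seq_len(heads), function(k) {
    list(W = glorot(d_out, d_in), a = stats::runif(2 * d_out, -0.1, 0.1))
  })
  names(hs) <- paste0("head", seq_len(heads))
  structure(list(heads = hs, d_in = as.integer(d_in), d_out = as.integer(d_out),
                 K = as.integer(heads), combine = combine,
                 negative_slope = negative_slope, activation = activation),
            class = "gat_params")
}

#' Raw attention score between two node feature vectors
#'
#' `e_ij = LeakyReLU(a^T [W h_i || W h_j])` for one head; not symmetric in
#' (i, j) because the two halves of `a` weight center and neighbor
#' differently.
#'
#' @param h_i,h_j node feature vectors of width `d_in`.
#' @param head one element of `gat_params$heads` (fields `W`, `a`).
#' @param negative_slope LeakyReLU slope (default 0.2).
#' @return scalar attention score.
#' @export
attention_score <- function(h_i, h_j, head, negative_slope = 0.2) {
  W <- head$W
  check_that(length(h_i) == ncol(W) && length(h_j) == ncol(W),
             "attention_score: feature width %d does not match W (%d cols)",
             length(h_i), ncol(W))
  z <- c(W %*% h_i, W %*% h_j)
  x <- sum(head$a * z)
  if (x >= 0) x else negative_slope * x
}

#' Normalize attention scores over a neighborhood
#'
#' Softmax with max-subtraction for overflow safety: weights are positive
#' and sum to one.
#'
#' @param scores numeric vector of raw scores over N(i); must be non-empty.
#' @return numeric vector of attention coefficients.
#' @export
attention_coefficients <- function(scores) {
  check_that(length(scores) >= 1,
             "attention_coefficients: empty neighborhood (missing self-loop?)")
  e <- exp(scores - max(scores))
  e / sum(e)
}

# rowsum into a dense n-row matrix (groups are 1-based node indices)
scatter_add <- function(V, idx, n) {
  rs <- rowsum(V, idx)
  out <- matrix(0, n, ncol(V))
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# Forward pass over a (possibly batched) node set. H: n x d_in; edges:
# m x 2 0-based (src = center i, dst = neighbor j), must include self-loops.
gat_fwd <- function(H, edges, params) {
  n <- nrow(H)
  src <- edges[, 1] + 1L
  dst <- edges[, 2] + 1L
  check_that(ncol(H) == params$d_in,
             "gat: feature width %d does not match layer d_in %d",
             ncol(H), params$d_in)
  check_that(all(seq_len(n) %in% src),
             "gat: some node has an empty neighborhood (missing self-loops)")
  heads <- vector("list", params$K)
  outs <- vector("list", params$K)
  slope <- params$negative_slope
  for (k in seq_len(params$K)) {
    hp <- params$heads[[k]]
    Z <- H %*% t(hp$W)                       # n x d_out
    d_out <- ncol(Z)
    s1 <- as.vector(Z %*% hp$a[seq_len(d_out)])
    s2 <- as.vector(Z %*% hp$a[d_out + seq_len(d_out)])
    pre <- s1[src] + s2[dst]
    e <- ifelse(pre > 0, pre, slope * pre)
    mx <- vapply(split(e, src), max, numeric(1))[as.character(src)]
    ex <- exp(e - mx)
    denom <- as.vector(scatter_add(cbind(ex), src, n))
    alpha <- ex / denom[src]
    S <- scatter_add(alpha * Z[dst, , drop = FALSE], src, n)
    a_out <- act_fwd(S, params$activation)
    heads[[k]] <- list(Z = Z, pre = pre, alpha = alpha, act = a_out)
    outs[[k]] <- a_out$Y
  }
  Y <- if (params$combine == "concat") do.call(cbind, outs)
       else Reduce(`+`, outs) / params$K
  list(Y = Y, heads = heads, H = H, src = src, dst = dst, n = n)
}

gat_bwd <- function(dY, cache, params) {
  n <- cache$n
  src <- cache$src
  dst <- cache$dst
  slope <- params$negative_slope
  d_out <- params$d_out
  dH <- cache$H * 0
  ghead <- vector("list", params$K)
  for (k in seq_len(params$K)) {
    hc <- cache$heads[[k]]
    hp <- params$heads[[k]]
    dOut <- if (params$combine == "concat") {
      dY[, (k - 1L) * d_out + seq_len(d_out), drop = FALSE]
    } else {
      dY / params$K
    }
    dS <- act_bwd(dOut, hc$act, params$activation)
    Zd <- hc$Z[dst, , drop = FALSE]
    dalpha <- rowSums(dS[src, , drop = FALSE] * Zd)
    dZ <- scatter_add(hc$alpha * dS[src, , drop = FALSE], dst, n)
    csum <- as.vector(scatter_add(cbind(hc$alpha * dalpha), src, n))
    de <- hc$alpha * (dalpha - csum[src])
    dpre <- de * ifelse(hc$pre > 0, 1, slope)
    ds1 <- as.vector(scatter_add(cbind(dpre), src, n))
    ds2 <- as.vector(scatter_add(cbind(dpre), dst, n))
    a1 <- hp$a[seq_len(d_out)]
    a2 <- hp$a[d_out + seq_len(d_out)]
    dZ <- dZ + outer(ds1, a1) + outer(ds2, a2)
    da <- c(colSums(hc$Z * ds1), colSums(hc$Z * ds2))
    dW <- t(dZ) %*% cache$H
    dH <- dH + dZ %*% hp$W
    ghead[[k]] <- list(W = dW, a = da)
  }
  names(ghead) <- names(params$heads)
  list(dH = dH, grads = list(heads = ghead))
}

#' Run one graph attention layer over a molecular graph
#'
#' Applies feature dropout to the input node features (training mode only),
#' then the multi-head attention update, returning the per-node embedding
#' matrix (and optionally the attention coefficients of every head).
#'
#' @param graph a `molecular_graph`, or any list with `node_features` and
#'   0-based `edges` including self-loops.
#' @param params a [gat_params()].
#' @param dropout_rate feature dropout rate applied to the input.
#' @param training logical; dropout is active only when TRUE.
#' @param return_attention also return per-head attention coefficients and
#'   the edge list they live on.
#' @return node embedding matrix (n_atoms x K*d_out for concat), or a list
#'   with `embedding` and `attention` when `return_attention` is TRUE.
#' @export
gat_layer_forward <- function(graph, params, dropout_rate = 0,
                              training = FALSE, return_attention = FALSE) {
  H <- graph$node_features
  dp <- dropout_fwd(H, dropout_rate, training)
  out <- gat_fwd(dp$Y, graph$edges, params)
  if (!return_attention) return(out$Y)
  list(
    embedding = out$Y,
    attention = lapply(out$heads, `[[`, "alpha"),
    src = out$src, dst = out$dst
  )
}
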