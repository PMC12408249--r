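# small helpers for hand-built graphs
path2 <- function() {
  rbind(c(0L, 1L), c(1L, 0L), c(0L, 0L), c(1L, 1L))
}
path3 <- function() {
  rbind(c(0L, 1L), c(1L, 0L), c(1L, 2L), c(2L, 1L),
        c(0L, 0L), c(1L, 1L), c(2L, 2L))
}
set_head <- function(params, k, W, a) {
  params$heads[[k]]$W <- W
  params$heads[[k]]$a <- a
  params
}

test_that("attention scores match hand evaluation", {
  p <- gat_params(1, 1, heads = 1)
  p <- set_head(p, 1, matrix(1, 1, 1), c(1, 2))
  # W h_i = 1, W h_j = 1 -> a^T [1 || 1] = 3, positive branch
  expect_equal(attention_score(1, 1, p$heads[[1]], 0.2), 3)
  # zero attention vector
  p0 <- set_head(p, 1, matrix(1, 1, 1), c(0, 0))
  expect_equal(attention_score(5, -2, p0$heads[[1]]), 0)
  # zero features
  expect_equal(attention_score(0, 0, p$heads[[1]]), 0)
  # negative pre-activation goes through the leaky slope
  pn <- set_head(p, 1, matrix(1, 1, 1), c(-1, -2))
  expect_equal(attention_score(1, 1, pn$heads[[1]], 0.2), 0.2 * -3)
  expect_error(attention_score(c(1, 2), 1, p$heads[[1]]), "width")
})

test_that("attention coefficients are a safe softmax", {
  expect_equal(attention_coefficients(7), 1)
  expect_equal(attention_coefficients(rep(2, 5)), rep(1 / 5, 5))
  expect_equal(attention_coefficients(c(0, log(2))), c(1 / 3, 2 / 3))
  expect_equal(sum(attention_coefficients(c(1e4, 1e4 + 1))), 1)  # no overflow
  expect_error(attention_coefficients(numeric(0)), "empty neighborhood")
})

test_that("a single node with a self-loop returns sigma(W h)", {
  p <- gat_params(2, 3, heads = 1, activation = "identity")
  g <- list(node_features = matrix(c(1.5, -2), 1, 2),
            edges = rbind(c(0L, 0L)))
  out <- gat_layer_forward(g, p)
  expect_equal(as.vector(out), as.vector(p$heads[[1]]$W %*% c(1.5, -2)))
})

test_that("a 2-node path matches a by-hand softmax aggregation", {
  w <- 0.7; a1 <- 0.3; a2 <- -0.5; h <- c(1.2, -0.4); slope <- 0.2
  p <- gat_params(1, 1, heads = 1, activation = "identity",
                  negative_slope = slope)
  p <- set_head(p, 1, matrix(w, 1, 1), c(a1, a2))
  g <- list(node_features = matrix(h, 2, 1), edges = path2())
  out <- as.vector(gat_layer_forward(g, p))

  lrelu <- function(x) ifelse(x > 0, x, slope * x)
  z <- w * h
  hand <- sapply(1:2, function(i) {
    nb <- c(i, setdiff(1:2, i))          # self + other
    e <- lrelu(a1 * z[i] + a2 * z[nb])
    alpha <- exp(e - max(e)) / sum(exp(e - max(e)))
    sum(alpha * z[nb])
  })
  expect_equal(out, hand, tolerance = 1e-12)
})

test_that("head combination controls the output width", {
  g <- list(node_features = matrix(rnorm(12), 3, 4), edges = path3())
  pc <- gat_params(4, 5, heads = 3, combine = "concat")
  expect_equal(dim(gat_layer_forward(g, pc)), c(3, 15))
  pa <- gat_params(4, 5, heads = 3, combine = "average")
  expect_equal(dim(gat_layer_forward(g, pa)), c(3, 5))
})

test_that("attention coefficients sum to one per node and head", {
  set.seed(2)
  g <- smiles_to_graph("CCOC(=O)Cc1ccccc1")
  p <- gat_params(ncol(g$node_features), 6, heads = 4)
  out <- gat_layer_forward(g, p, return_attention = TRUE)
  for (alpha in out$attention) {
    sums <- tapply(alpha, out$src, sum)
    expect_equal(as.vector(sums), rep(1, g$n_atoms), tolerance = 1e-6)
  }
})

test_that("the layer is permutation equivariant", {
  set.seed(3)
  g <- smiles_to_graph("CCNC(=O)CC")
  n <- g$n_atoms
  p <- gat_params(ncol(g$node_features), 4, heads = 2)
  Y <- gat_layer_forward(g, p)
  perm <- sample.int(n)                 # perm[old + 1] = new 1-based index
  g2 <- list(node_features = g$node_features[order(perm), , drop = FALSE],
             edges = cbind(perm[g$edges[, 1] + 1L] - 1L,
                           perm[g$edges[, 2] + 1L] - 1L))
  Y2 <- gat_layer_forward(g2, p)
  expect_equal(Y2[perm, , drop = FALSE], Y, tolerance = 1e-12)
})

test_that("equal features on a regular graph give equal rows", {
  # 4-cycle with self-loops, all node features identical
  edges <- rbind(c(0, 1), c(1, 0), c(1, 2), c(2, 1), c(2, 3), c(3, 2),
                 c(3, 0), c(0, 3), c(0, 0), c(1, 1), c(2, 2), c(3, 3))
  g <- list(node_features = matrix(rep(c(0.4, -1, 2), each = 4), 4, 3),
            edges = edges)
  p <- gat_params(3, 5, heads = 2)
  Y <- gat_layer_forward(g, p)
  expect_equal(max(apply(Y, 2, function(col) diff(range(col)))), 0,
               tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences on 3 nodes", {
  set.seed(42)
  edges <- path3()
  H <- matrix(rnorm(12), 3, 4)
  params <- gat_params(4, 3, heads = 2, combine = "concat")
  R <- matrix(rnorm(9 * 2), 3, 6)       # fixed projection -> scalar loss
  loss_fn <- function(pp, HH) sum(bsinet:::gat_fwd(HH, edges, pp)$Y * R)
  fw <- bsinet:::gat_fwd(H, edges, params)
  bw <- bsinet:::gat_bwd(R, fw, params)
  relerr <- function(a, b) max(abs(a - b)) / max(1e-8, max(abs(a)),
                                                 max(abs(b)))
  eps <- 1e-6
  num_grad <- function(x, apply_x) {
    g <- x * 0
    for (i in seq_along(x)) {
      xp <- x; xp[i] <- x[i] + eps
      xm <- x; xm[i] <- x[i] - eps
      g[i] <- (apply_x(xp) - apply_x(xm)) / (2 * eps)
    }
    g
  }
  for (k in 1:2) {
    gW <- num_grad(params$heads[[k]]$W, function(v) {
      pp <- params; pp$heads[[k]]$W <- matrix(v, 3, 4); loss_fn(pp, H)
    })
    expect_lt(relerr(gW, bw$grads$heads[[k]]$W), 1e-4)
    ga <- num_grad(params$heads[[k]]$a, function(v) {
      pp <- params; pp$heads[[k]]$a <- v; loss_fn(pp, H)
    })
    expect_lt(relerr(ga, bw$grads$heads[[k]]$a), 1e-4)
  }
  gH <- num_grad(H, function(v) loss_fn(params, matrix(v, 3, 4)))
  expect_lt(relerr(gH, bw$dH), 1e-4)
})
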