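test_that("Tanimoto handles identity, disjoint and overlap cases", {
  m <- tanimoto_similarity(list(a = c(1, 2, 3), b = c(2, 3, 4),
                                c = c(9, 10), d = c(1, 2, 3)))
  expect_equal(m["a", "a"], 1)
  expect_equal(m["a", "d"], 1)
  expect_equal(m["a", "c"], 0)
  expect_equal(m["a", "b"], 0.5)   # |{2,3}| / |{1,2,3,4}|
  expect_equal(unclass(m), t(unclass(m)), ignore_attr = TRUE)
})

test_that("empty fingerprints score zero everywhere, including the diagonal", {
  m <- tanimoto_similarity(list(a = integer(0), b = c(1, 2)))
  expect_equal(m["a", "a"], 0)
  expect_equal(m["a", "b"], 0)
  expect_equal(m["b", "b"], 1)
})

test_that("Tanimoto agrees with a brute-force set oracle on 100 random pairs", {
  set.seed(101)
  fps <- lapply(1:100, function(i) {
    sample.int(256, sample(0:40, 1)) - 1L
  })
  m <- tanimoto_similarity(fps)
  for (t in 1:100) {
    i <- sample.int(100, 1)
    j <- sample.int(100, 1)
    expected <- if (length(fps[[i]]) == 0 || length(fps[[j]]) == 0) 0
                else tanimoto_oracle(fps[[i]], fps[[j]])
    expect_equal(m[i, j], expected)
  }
  expect_true(all(m >= 0 & m <= 1))
})

test_that("interaction cosine matches direct dot-product computation", {
  M <- rbind(a = c(1, 1, 0), b = c(1, 0, 1), c = c(0, 0, 0))
  s <- interaction_cosine(M)
  expect_equal(s["a", "b"], 0.5)         # 1 / (sqrt(2) * sqrt(2))
  expect_equal(s["a", "a"], 1)
  expect_equal(s["c", "c"], 0)           # no targets -> no evidence
  expect_equal(s["a", "c"], 0)

  set.seed(55)
  B <- matrix(rbinom(30 * 12, 1, 0.3), 30, 12)
  sb <- interaction_cosine(B)
  for (t in 1:50) {
    i <- sample.int(30, 1); j <- sample.int(30, 1)
    ni <- sqrt(sum(B[i, ]^2)); nj <- sqrt(sum(B[j, ]^2))
    expected <- if (ni == 0 || nj == 0) 0 else {
      if (i == j) 1 else sum(B[i, ] * B[j, ]) / (ni * nj)
    }
    expect_equal(sb[i, j], expected, tolerance = 1e-12)
  }
  expect_equal(unclass(sb), t(unclass(sb)), ignore_attr = TRUE)
  expect_true(all(sb >= 0 & sb <= 1))
})

test_that("global alignment similarity matches the DP oracle and is normalized", {
  seqs <- c(d1 = "HEAGAWGHEE", d2 = "PAWHEAE", d3 = "AAAA", d4 = "WWWW")
  m <- global_alignment_similarity(seqs)
  expect_equal(diag(unclass(m)), rep(1, 4), ignore_attr = TRUE)
  expect_equal(unclass(m), t(unclass(m)), ignore_attr = TRUE)
  expect_lt(m["d3", "d4"], 1)

  sub <- blosum62_matrix()
  s12 <- nw_oracle_score("HEAGAWGHEE", "PAWHEAE", sub)
  s11 <- nw_oracle_score("HEAGAWGHEE", "HEAGAWGHEE", sub)
  s22 <- nw_oracle_score("PAWHEAE", "PAWHEAE", sub)
  expected <- min(max(s12 / sqrt(s11 * s22), 0), 1)
  expect_equal(m["d1", "d2"], expected, tolerance = 1e-12)
})

test_that("empty sequences are rejected by name", {
  expect_error(global_alignment_similarity(c(ok = "AAA", bad = "")), "bad")
})

test_that("fused blocks are plain sums with strict shape/id checking", {
  ids <- c("a", "b")
  I <- matrix(c(0, 1, 1, 0), 2, dimnames = list(ids, ids))
  T_ <- matrix(0.5, 2, 2, dimnames = list(ids, ids))
  S <- matrix(c(1, 0.3, 0.3, 1), 2, dimnames = list(ids, ids))
  F_ <- fuse_feature_block(I, T_, S)
  expect_equal(F_["a", "b"], 1 + 0.5 + 0.3)
  expect_equal(F_, unclass(I) + unclass(T_) + unclass(S))
  expect_true(all(F_ >= 0 & F_ <= 3))

  expect_equal(fuse_feature_block(I, I * 0, I * 0), unclass(I))
  expect_error(fuse_feature_block(I, T_, matrix(0, 3, 3)), "shape")
  bad_ids <- matrix(0.5, 2, 2, dimnames = list(c("b", "a"), c("b", "a")))
  expect_error(fuse_feature_block(I, T_, bad_ids), "id order")
})

test_that("interaction_matrix validates endpoints and symmetrizes", {
  edges <- data.frame(a = c("d1", "d2"), b = c("d2", "d3"))
  m <- interaction_matrix(edges, c("d1", "d2", "d3"), symmetric = TRUE)
  expect_equal(m["d1", "d2"], 1)
  expect_equal(m["d2", "d1"], 1)
  expect_equal(diag(m), c(d1 = 0, d2 = 0, d3 = 0))
  expect_error(
    interaction_matrix(data.frame(a = "d1", b = "nope"), c("d1", "d2"),
                       symmetric = TRUE),
    "nope")
})
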