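test_that("stratified folds preserve class proportions exactly when divisible", {
  f1 <- stratified_folds(rep(0, 100), k = 10, seed = 1)
  expect_equal(unname(table(f1$assignments)), rep(10L, 10),
               ignore_attr = TRUE)

  labels <- rep(c("a", "b", "c"), times = c(50, 30, 20))
  f2 <- stratified_folds(labels, k = 10, seed = 2)
  tab <- table(labels, f2$assignments)
  expect_true(all(tab["a", ] == 5))
  expect_true(all(tab["b", ] == 3))
  expect_true(all(tab["c", ] == 2))
})

test_that("fold class counts stay within one example of proportionality", {
  set.seed(33)
  labels <- sample(0:4, 437, replace = TRUE, prob = c(0.4, 0.3, 0.15, 0.1, 0.05))
  k <- 7
  plan <- stratified_folds(labels, k, seed = 5)
  tab <- table(labels, plan$assignments)
  for (cl in rownames(tab)) {
    expect_lte(diff(range(tab[cl, ])), 1)
  }
  expect_equal(length(plan$assignments), length(labels))
})

test_that("fold seeds change assignments but never class counts", {
  labels <- rep(0:2, times = c(40, 30, 20))
  fa <- stratified_folds(labels, 5, seed = 1)
  fb <- stratified_folds(labels, 5, seed = 2)
  expect_false(identical(fa$assignments, fb$assignments))
  expect_equal(table(labels, fa$assignments), table(labels, fb$assignments))
  expect_identical(fa$assignments,
                   stratified_folds(labels, 5, seed = 1)$assignments)
})

test_that("classes smaller than k are rejected by name", {
  expect_error(stratified_folds(c(rep("big", 20), "rare"), k = 5), "rare")
})

test_that("perfect predictions score one everywhere", {
  y <- rep(0:2, times = c(5, 3, 2))
  rep_ <- metrics_report(y, y, n_classes = 3)
  for (r in c("micro", "macro", "weighted")) {
    expect_equal(rep_[[r]]$precision, 1)
    expect_equal(rep_[[r]]$recall, 1)
    expect_equal(rep_[[r]]$f1, 1)
  }
  expect_equal(rep_$micro$mcc, 1)
})

test_that("macro metrics match hand arithmetic on a printed toy matrix", {
  # confusion [[2,0,0],[1,1,0],[0,0,2]]: true class 0 twice -> predicted 0;
  # true class 1 -> once predicted 0, once 1; true class 2 twice -> 2
  y_true <- c(0, 0, 1, 1, 2, 2)
  y_pred <- c(0, 0, 0, 1, 2, 2)
  m <- evaluate(y_true, y_pred, regime = "macro", n_classes = 3)
  expect_equal(unclass(m$confusion),
               rbind(c(2, 0, 0), c(1, 1, 0), c(0, 0, 2)),
               ignore_attr = TRUE)
  expect_equal(m$precision, (2 / 3 + 1 + 1) / 3)
  expect_equal(m$recall, (1 + 1 / 2 + 1) / 3)
})

test_that("micro precision = recall = F1 = accuracy, and weighted recall too", {
  set.seed(9)
  y <- sample(0:3, 200, replace = TRUE)
  yhat <- ifelse(runif(200) < 0.7, y, sample(0:3, 200, replace = TRUE))
  mi <- evaluate(y, yhat, regime = "micro", n_classes = 4)
  expect_equal(mi$precision, mi$accuracy)
  expect_equal(mi$recall, mi$accuracy)
  expect_equal(mi$f1, mi$accuracy)
  w <- evaluate(y, yhat, regime = "weighted", n_classes = 4)
  expect_equal(w$recall, w$accuracy)
})

test_that("multiclass MCC reduces to binary MCC on two classes", {
  cm <- rbind(c(37, 8), c(5, 50))
  tp <- 50; tn <- 37; fp <- 8; fn <- 5
  binary <- (tp * tn - fp * fn) /
    sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  expect_equal(multiclass_mcc(cm), binary)
  expect_gte(multiclass_mcc(cm), -1)
  expect_lte(multiclass_mcc(cm), 1)
})

test_that("uniform random predictions give MCC near zero", {
  set.seed(77)
  y <- sample(0:4, 4000, replace = TRUE)
  yhat <- sample(0:4, 4000, replace = TRUE)
  expect_lt(abs(evaluate(y, yhat, regime = "micro", n_classes = 5)$mcc),
            0.05)
})

test_that("AUROC agrees with an independent implementation, AUPR is sane", {
  skip_if_not_installed("pROC")
  set.seed(13)
  truth <- rbinom(300, 1, 0.3)
  score <- truth * 0.5 + rnorm(300)
  ours <- binary_auroc(truth, score)
  ref <- suppressMessages(as.numeric(pROC::auc(truth, score)))
  expect_equal(ours, ref, tolerance = 1e-10)

  # perfect separation
  expect_equal(binary_auroc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(binary_aupr(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  # prevalence is the chance-level AUPR
  set.seed(14)
  t2 <- rbinom(5000, 1, 0.2)
  expect_equal(binary_aupr(t2, runif(5000)), 0.2, tolerance = 0.05)
})

test_that("train_fold honors the epoch budget and the loss threshold", {
  ds <- tiny_dataset()
  cfg <- config_for_dataset(ds, gat1_out = 4L, gat1_heads = 2L,
                            gat2_out = 4L, gat2_heads = 2L, fc_out = 8L,
                            mlp_hidden = c(16L, 8L), max_epochs = 0L)
  net <- bsinet_init(cfg, ds$d_atom, seed = 2L)
  fit0 <- train_fold(net, ds, seq_len(50), seed = 2L)
  expect_equal(nrow(fit0$trace), 0L)

  cfg1 <- config_for_dataset(ds, gat1_out = 4L, gat1_heads = 2L,
                             gat2_out = 4L, gat2_heads = 2L, fc_out = 8L,
                             mlp_hidden = c(16L, 8L), max_epochs = 5L,
                             epsilon = 100)      # above any initial loss
  net1 <- bsinet_init(cfg1, ds$d_atom, seed = 2L)
  fit1 <- train_fold(net1, ds, seq_len(50), seed = 2L)
  expect_equal(nrow(fit1$trace), 1L)
  expect_error(train_fold(net1, ds, integer(0)), "empty training set")
})

test_that("cross-validation scores every example exactly once out-of-fold", {
  ds <- tiny_dataset()
  res <- run_cv(ds, k = 2, seed = 4, model = "random_forest")
  expect_false(anyNA(res$prob_matrix))
  expect_equal(nrow(res$prob_matrix), nrow(ds$pairs))
  expect_equal(rowSums(res$prob_matrix), rep(1, nrow(ds$pairs)),
               tolerance = 1e-6)
  # reproducibility: identical seed, identical report
  res2 <- run_cv(ds, k = 2, seed = 4, model = "random_forest")
  expect_equal(res$pooled$weighted$f1, res2$pooled$weighted$f1)
  expect_identical(res$fold_plan$assignments, res2$fold_plan$assignments)
  expect_equal(res$prob_matrix, res2$prob_matrix)
  # fold summary carries mean and sd per regime
  expect_true(all(c("regime", "metric", "mean", "sd") %in%
                    names(res$fold_summary)))
})
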