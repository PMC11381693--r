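test_that("loss matrix from outcome proportions balances the classes", {
  expect_equal(loss_from_proportions(0.5)$fn_penalty, 1)
  expect_equal(loss_from_proportions(0.21)$fn_penalty, 0.79 / 0.21)
  expect_equal(loss_from_proportions(0.2324)$fn_penalty, 0.7676 / 0.2324)
  expect_equal(loss_from_proportions(0.25, multiplier = 2)$fn_penalty, 6)
  expect_error(loss_from_proportions(0), "strictly inside")
  expect_error(loss_from_proportions(1), "strictly inside")
  expect_error(loss_matrix(-1), "positive")
})

test_that("weighted Gini impurity follows the altered-priors definition", {
  expect_equal(gini_impurity(50, 50), 0.5)
  expect_equal(gini_impurity(100, 0), 0)
  expect_equal(gini_impurity(0, 100, loss_matrix(3)), 0)
  # weights (1-p)/p rebalance exactly: weighted positive fraction 1/2
  expect_equal(gini_impurity(79, 21, loss_matrix(79 / 21)), 0.5)
})

test_that("degenerate and perfectly separable data give the expected trees", {
  X <- matrix(rbinom(200, 1, 0.5), 100, 2, dimnames = list(NULL, c("a", "b")))
  t0 <- fit_tree(X, rep(0L, 100))
  expect_equal(nrow(t0$nodes), 1L)
  expect_false(t0$nodes$predicted)

  y <- X[, "a"]
  t1 <- fit_tree(X, y)
  expect_equal(t1$nodes$split[1], "a")
  expect_equal(max(t1$nodes$depth), 1L)
  leaves <- t1$nodes[is.na(t1$nodes$split), ]
  expect_true(all(leaves$n_at_risk %in% c(0L, leaves$n)))  # pure leaves
})

test_that("leaf prediction uses the loss-weighted threshold, not 0.5", {
  # a single leaf with 30% positives: negative under unit loss, positive
  # once fn/(fn+fp) pushes the operative threshold below 0.3
  X <- matrix(0L, 100, 1, dimnames = list(NULL, "a"))
  y <- c(rep(1L, 30), rep(0L, 70))
  expect_false(fit_tree(X, y, loss_matrix(1))$nodes$predicted[1])
  expect_true(fit_tree(X, y, loss_matrix(3))$nodes$predicted[1])
})

test_that("structural constraints hold on fitted trees", {
  d <- random_binary_dataset(800, 6, seed = 31)
  loss <- loss_from_proportions(mean(d$y))
  hp <- tree_hyperparams(max_depth = 4, min_node_size = 25)
  tr <- fit_tree(d$X, d$y, loss, hp)
  nd <- tr$nodes
  internal <- nd[!is.na(nd$split), ]
  # children partition the parent
  expect_equal(nd$n[internal$child_absent] + nd$n[internal$child_present],
               internal$n)
  expect_true(all(nd$n[is.na(nd$split)] >= 25))
  expect_true(all(nd$depth <= 4))
  # no condition repeats on a root-to-leaf path
  for (leaf in nd$id[is.na(nd$split)]) {
    path <- character(0); j <- leaf
    while (!is.na(nd$parent[j])) { j <- nd$parent[j]; path <- c(path, nd$split[j]) }
    expect_false(anyDuplicated(path) > 0)
  }
})

test_that("greedy expected loss is achievable by exhaustive enumeration", {
  hp <- tree_hyperparams(max_depth = 2, min_node_size = 25)
  for (s in 1:20) {
    d <- random_binary_dataset(60, 4, seed = 100 + s)
    loss <- if (mean(d$y) %in% c(0, 1)) loss_matrix(1) else
      loss_from_proportions(mean(d$y))
    tr <- fit_tree(d$X, d$y, loss, hp)
    greedy <- sarcomb:::tree_expected_loss(tr, d$X, d$y)
    attainable <- enumerate_depth2_losses(d$X, d$y, loss$fn_penalty,
                                          loss$fp_penalty)
    expect_true(any(abs(attainable - greedy) < 1e-9))
    gains <- root_gini_gains(d$X, d$y, loss$fn_penalty, loss$fp_penalty)
    best <- max(gains)
    if (is.finite(best) && best > 0 && sum(gains > best - 1e-12) == 1L) {
      expect_equal(greedy, min(attainable), tolerance = 1e-9)
    }
  }
})

test_that("raising the false-negative penalty never lowers sensitivity", {
  d <- random_binary_dataset(600, 5, seed = 77)
  hp <- tree_hyperparams(max_depth = 5, min_node_size = 25)
  sens <- vapply(c(1, 2, 4, 8), function(fn) {
    tr <- fit_tree(d$X, d$y, loss_matrix(fn), hp)
    pred <- predict(tr, d$X)$class
    sum(pred & d$y == 1) / sum(d$y == 1)
  }, numeric(1))
  expect_true(all(diff(sens) >= 0))
})

test_that("unit-loss trees beat the majority-class constant predictor", {
  for (s in 1:5) {
    d <- random_binary_dataset(400, 5, seed = 200 + s)
    tr <- fit_tree(d$X, d$y, loss_matrix(1),
                   tree_hyperparams(max_depth = 10, min_node_size = 5))
    miscl <- sarcomb:::tree_expected_loss(tr, d$X, d$y)
    expect_lte(miscl, min(sum(d$y), sum(1 - d$y)))
  }
})

test_that("prediction is self-consistent, batch-invariant and validated", {
  d <- random_binary_dataset(300, 4, seed = 12)
  tr <- fit_tree(d$X, d$y, loss_matrix(2), tree_hyperparams(max_depth = 3))
  pr <- predict(tr, d$X)
  # leaf routing reproduces the stored node counts
  leaf_counts <- table(factor(pr$leaf, levels = tr$nodes$id))
  leaves <- is.na(tr$nodes$split)
  expect_equal(as.integer(leaf_counts[leaves]), tr$nodes$n[leaves])
  expect_true(all(leaf_counts[!leaves] == 0))
  # batch vs row-at-a-time
  rowwise <- vapply(seq_len(50), function(i) {
    predict(tr, d$X[i, , drop = FALSE])$class
  }, logical(1))
  expect_identical(rowwise, pr$class[1:50])
  # an all-zeros row follows the absent branches to one leaf
  zero <- matrix(0L, 1, 4, dimnames = list(NULL, colnames(d$X)))
  expect_length(predict(tr, zero)$leaf, 1L)
  expect_error(predict(tr, d$X[, 1:2, drop = FALSE]), "missing columns")
})

test_that("trees survive a JSON round trip", {
  d <- random_binary_dataset(300, 4, seed = 8)
  tr <- fit_tree(d$X, d$y, loss_from_proportions(mean(d$y)))
  back <- tree_from_json(tree_to_json(tr))
  expect_equal(back$nodes, tr$nodes)
  expect_identical(predict(back, d$X), predict(tr, d$X))
})

test_that("fits agree with rpart under matched cost-sensitive settings", {
  library(rpart)
  for (s in 1:5) {
    d <- random_binary_dataset(500, 4, seed = 300 + s)
    p <- mean(d$y)
    loss <- loss_from_proportions(p)
    hp <- tree_hyperparams(max_depth = 4, min_node_size = 25)
    mine <- fit_tree(d$X, d$y, loss, hp)
    df <- data.frame(y = factor(d$y, levels = 0:1), d$X)
    rp <- rpart(y ~ ., data = df, method = "class",
                parms = list(loss = matrix(c(0, loss$fn_penalty,
                                             loss$fp_penalty, 0), 2, 2),
                             split = "gini"),
                control = rpart.control(maxdepth = 4, minbucket = 25,
                                        minsplit = 50, cp = 0, xval = 0,
                                        maxsurrogate = 0, maxcompete = 0))
    mine_loss <- sarcomb:::tree_expected_loss(mine, d$X, d$y)
    rp_pred <- predict(rp, df, type = "class") == "1"
    rp_loss <- sum(ifelse(d$y == 1 & !rp_pred, loss$fn_penalty,
                          ifelse(d$y == 0 & rp_pred, loss$fp_penalty, 0)))
    expect_equal(mine_loss, rp_loss, tolerance = 1e-8)
  }
})
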