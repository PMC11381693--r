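# Hand-built trees with known leaf counts, for exact scoring semantics.
mk_tree <- function(nodes, features) {
  structure(list(nodes = nodes,
                 meta = list(n_train = sum(nodes$n[nodes$parent %in% NA]),
                             loss = loss_matrix(1), hyperparams = tree_hyperparams(),
                             features = features)),
            class = "ltc_tree")
}

depth1_tree <- function(feature, n, n_pos_present, n_present,
                        absent_pred = FALSE) {
  mk_tree(data.frame(
    id = 1:3, depth = c(0L, 1L, 1L), parent = c(NA, 1L, 1L),
    split = c(feature, NA, NA),
    child_absent = c(2L, NA, NA), child_present = c(3L, NA, NA),
    n = c(n, n - n_present, n_present),
    n_at_risk = c(n_pos_present + 5L, 5L, n_pos_present),
    predicted = c(FALSE, absent_pred, TRUE), stringsAsFactors = FALSE),
    features = feature)
}

test_that("rule extraction reads at-risk root-to-leaf paths", {
  X <- matrix(c(rep(1L, 50), rep(0L, 50)), 100, 1,
              dimnames = list(NULL, "osteoarthritis"))
  y <- as.integer(X[, 1])
  tr <- fit_tree(X, y, loss_matrix(1), tree_hyperparams(min_node_size = 10))
  rules <- extract_rules(tr, tree_index = 7L)
  expect_length(rules, 1L)
  expect_equal(rules[[1]]$literals,
               data.frame(condition_id = "osteoarthritis",
                          required = "present", stringsAsFactors = FALSE))
  expect_equal(rules[[1]]$tree_index, 7L)

  # a tree with no at-risk leaf yields no rules
  t0 <- fit_tree(X, rep(0L, 100))
  expect_length(extract_rules(t0), 0L)

  # depth-2 conjunction: both conditions on the path, in order
  set.seed(1)
  X2 <- cbind(diabetes = rbinom(400, 1, 0.5), stroke = rbinom(400, 1, 0.5))
  y2 <- as.integer(X2[, "diabetes"] & X2[, "stroke"])
  t2 <- fit_tree(X2, y2, loss_matrix(1), tree_hyperparams(min_node_size = 10))
  paths <- lapply(extract_rules(t2), function(r) r$literals)
  joint <- Filter(function(p) all(p$required == "present"), paths)
  expect_length(joint, 1L)
  expect_setequal(joint[[1]]$condition_id, c("diabetes", "stroke"))
})

test_that("positive-literal reduction discards negative diagnoses", {
  rule <- list(literals = data.frame(
    condition_id = c("diabetes", "hypertension", "stroke"),
    required = c("present", "absent", "present"), stringsAsFactors = FALSE))
  expect_equal(reduce_to_positive(rule), c("diabetes", "stroke"))
  all_neg <- list(literals = data.frame(condition_id = "hypertension",
                                        required = "absent",
                                        stringsAsFactors = FALSE))
  expect_length(reduce_to_positive(all_neg), 0L)
})

test_that("composite scores sum leaf correct-classification probabilities", {
  # one tree, one at-risk leaf 40/80 reducing to {A} -> score 0.5
  e1 <- structure(list(trees = list(depth1_tree("A", 200L, 40L, 80L))),
                  class = "ltc_ensemble")
  r1 <- composite_scores(e1)
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$composite_score, 0.5)
  expect_equal(r1$label, "A and any other LTC")

  # tree with two at-risk leaves: (A present -> 60/100) reduces to {A};
  # (A absent, B present -> 40/100) reduces to {B} after dropping the
  # negative literal. A second tree contributes {A} again at 50/100.
  two_leaf <- mk_tree(data.frame(
    id = 1:5, depth = c(0L, 1L, 1L, 2L, 2L), parent = c(NA, 1L, 1L, 2L, 2L),
    split = c("A", "B", NA, NA, NA),
    child_absent = c(2L, 4L, NA, NA, NA), child_present = c(3L, 5L, NA, NA, NA),
    n = c(300L, 200L, 100L, 100L, 100L),
    n_at_risk = c(110L, 50L, 60L, 10L, 40L),
    predicted = c(FALSE, FALSE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE), features = c("A", "B"))
  e2 <- structure(list(trees = list(two_leaf, depth1_tree("A", 200L, 50L, 100L))),
                  class = "ltc_ensemble")
  r2 <- composite_scores(e2)
  a_row <- r2[vapply(r2$conditions, identical, logical(1), "A"), ]
  expect_equal(a_row$composite_score, 0.6 + 0.5)
  expect_equal(a_row$n_trees_appearing, 2L)
  b_row <- r2[vapply(r2$conditions, identical, logical(1), "B"), ]
  expect_equal(b_row$composite_score, 0.4)
  expect_equal(b_row$n_leaves, 1L)

  # empty ensemble
  e0 <- structure(list(trees = list()), class = "ltc_ensemble")
  expect_equal(nrow(composite_scores(e0)), 0L)
})

test_that("bootstrap ensembles are reproducible and constraint-respecting", {
  sim <- simulated_analytic(n_per_sex = 2000L, seed = 21)
  reg_f <- sarcomb:::registry_for_sex(sim$registry, "female")
  e1 <- bootstrap_ensemble(sim$cohort, reg_f, n_trees = 15, seed = 5)
  e2 <- bootstrap_ensemble(sim$cohort, reg_f, n_trees = 15, seed = 5)
  expect_identical(vapply(e1$trees, tree_to_json, character(1)),
                   vapply(e2$trees, tree_to_json, character(1)))
  for (tr in e1$trees) {
    expect_lte(max(tr$nodes$depth), 10L)
    expect_true(all(tr$nodes$n[is.na(tr$nodes$split)] >= 25L))
  }
  # per-tree loss recomputed from the resample's own outcome proportions
  p_b <- vapply(seq_along(e1$trees), function(t) {
    mean(sim$cohort$at_risk[e1$boot_index[[t]]])
  }, numeric(1))
  expect_equal(vapply(e1$loss, `[[`, numeric(1), "fn_penalty"),
               (1 - p_b) / p_b)

  # with bootstrap disabled and one tree, the ensemble is a plain fit
  e3 <- bootstrap_ensemble(sim$cohort, reg_f, n_trees = 1, seed = 5,
                           bootstrap = FALSE)
  direct <- fit_tree(as.matrix(sim$cohort[reg_f$condition_id]),
                     as.integer(sim$cohort$at_risk),
                     loss_from_proportions(mean(sim$cohort$at_risk)),
                     tree_hyperparams())
  expect_equal(e3$trees[[1]]$nodes, direct$nodes)

  # at-risk leaf sizes sum to the tree's predicted-positive count in-bag
  for (t in 1:3) {
    tr <- e1$trees[[t]]
    Xb <- as.matrix(sim$cohort[e1$boot_index[[t]], reg_f$condition_id])
    pred <- predict(tr, Xb)$class
    at_risk_leaves <- is.na(tr$nodes$split) & tr$nodes$predicted
    expect_equal(sum(tr$nodes$n[at_risk_leaves]), sum(pred))
  }
})

test_that("ranking orders by score with the documented tie-breaks", {
  recs <- structure(data.frame(
    label = c("a", "b", "c", "d"),
    n_trees_appearing = c(700L, 300L, 900L, 100L),
    n_leaves = 1L,
    composite_score = c(2.0, 2.0, 3.0, 1.0), stringsAsFactors = FALSE),
    class = c("combination_records", "data.frame"))
  recs$conditions <- list("a", "b", "c", "d")
  attr(recs, "n_trees") <- 1000L
  rk <- rank_and_retain(recs, k = 2)
  expect_equal(rk$label, c("c", "a", "b", "d"))  # tie: 700 trees beats 300
  expect_equal(rk$retained, c(TRUE, TRUE, FALSE, FALSE))
  expect_warning(rank_and_retain(recs, k = 10), "only 4")
})

test_that("combination metrics reproduce confusion-matrix arithmetic", {
  # exposed/at-risk cells: a=50, b=50, c=10, d=890
  counts <- data.frame(diabetes = c(1, 1, 0, 0), stroke = c(1, 1, 0, 0),
                       at_risk = c(1, 0, 1, 0), n = c(50, 50, 10, 890))
  co <- cohort_from_counts(counts)
  m <- evaluate_combination(co, c("diabetes", "stroke"))
  expect_equal(m$prevalence_pct, 10)
  expect_equal(m$ppv_pct, 50)
  expect_equal(m$sensitivity_pct, 100 * 50 / 60, tolerance = 1e-10)
  expect_equal(m$specificity_pct, 100 * 890 / 940, tolerance = 1e-10)
  expect_equal(m$accuracy_pct, 94)
  # accuracy identity: acc = sens*p + spec*(1-p)
  p <- mean(co$at_risk)
  expect_equal(m$accuracy_pct,
               m$sensitivity_pct * p + m$specificity_pct * (1 - p),
               tolerance = 1e-10)

  # exposure identical to the outcome: all metrics 100
  co2 <- cohort_from_counts(data.frame(diabetes = c(1, 0), at_risk = c(1, 0),
                                       n = c(30, 70)))
  m2 <- evaluate_combination(co2, "diabetes")
  expect_equal(unlist(m2[c("ppv_pct", "sensitivity_pct", "specificity_pct")]),
               c(ppv_pct = 100, sensitivity_pct = 100, specificity_pct = 100))

  # nobody exposed: prevalence 0, PPV missing
  co3 <- cohort_from_counts(data.frame(diabetes = 0, stroke = 1,
                                       at_risk = c(1, 0), n = c(10, 90)))
  m3 <- evaluate_combination(co3, c("diabetes", "stroke"))
  expect_equal(m3$prevalence_pct, 0)
  expect_true(is.na(m3$ppv_pct))
})

test_that("ensemble summaries count combinations and half-ensemble rules", {
  recs <- structure(data.frame(n_trees_appearing = c(600L, 400L, 900L)),
                    class = c("combination_records", "data.frame"))
  attr(recs, "n_trees") <- 1000L
  s <- ensemble_summary(recs)
  expect_equal(s$n_combinations, 3L)
  expect_equal(s$n_in_half, 2L)
  empty <- structure(data.frame(n_trees_appearing = integer(0)),
                     class = c("combination_records", "data.frame"))
  attr(empty, "n_trees") <- 1000L
  expect_equal(ensemble_summary(empty)$n_combinations, 0L)
  expect_equal(ensemble_summary(empty)$n_in_half, 0L)
})

test_that("combination counts match binomial coefficients", {
  expect_equal(count_combinations(53, 2), 1378)
  expect_equal(count_combinations(53, 3), 23426)
  expect_gt(count_combinations(53, 10, cumulative = TRUE), 1e10)
  expect_error(count_combinations(-1, 2), "non-negative")
  expect_error(count_combinations(5, 9), "exceeds")
})
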