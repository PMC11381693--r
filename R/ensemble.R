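#' Fit a bagged ensemble of cost-sensitive trees
#'
#' Fits `n_trees` trees, each on a with-replacement bootstrap resample of the
#' single-sex analytic cohort. By default the loss matrix is recomputed from
#' each bootstrap sample's own outcome proportions (it is derived directly
#' from the proportions of the two outcomes); `freeze_loss = TRUE` keeps the
#' full-sample value for every tree. One child seed is drawn per tree from
#' the master seed, so ensembles are reproducible and per-tree work is
#' order-independent.
#'
#' @param cohort Restricted, classified, single-sex cohort.
#' @param registry Registry defining the feature columns (use a reduced
#'   registry view to exclude conditions).
#' @param hp Tree hyperparameters.
#' @param n_trees Ensemble size (the reference analysis uses 1000).
#' @param seed Master seed (mandatory).
#' @param fn_multiplier Multiplier on the false-negative penalty (the doubled
#'   penalty sensitivity analysis uses 2).
#' @param freeze_loss Use the full-sample loss matrix for every tree.
#' @param bootstrap Set `FALSE` to fit every tree on the full sample (test
#'   hook; with `n_trees = 1` this equals a single [fit_tree()] call).
#' @return A list of class `ltc_ensemble`: `trees` (list of `ltc_tree`),
#'   `boot_index` (list of integer resample indices), `loss` (per-tree loss
#'   matrices), `meta`.
#' @export
bootstrap_ensemble <- function(cohort, registry, hp = tree_hyperparams(),
                               n_trees = 1000L, seed, fn_multiplier = 1,
                               freeze_loss = FALSE, bootstrap = TRUE) {
  if (missing(seed)) stop("seed is mandatory")
  sexes <- unique(cohort$sex)
  if (length(sexes) != 1L) stop("ensemble expects a single-sex cohort")
  ids <- condition_cols(cohort, registry)
  X <- as.matrix(cohort[ids])
  y <- as.integer(cohort$at_risk)
  if (anyNA(y)) stop("cohort contains unclassified participants; restrict first")
  n <- nrow(X)
  p_full <- mean(y)
  full_loss <- loss_from_proportions(p_full, multiplier = fn_multiplier)

  set.seed(as.integer(seed))
  child_seeds <- sample.int(.Machine$integer.max, n_trees)
  trees <- vector("list", n_trees)
  boot_index <- vector("list", n_trees)
  losses <- vector("list", n_trees)
  n_single_class <- 0L
  for (t in seq_len(n_trees)) {
    set.seed(child_seeds[t])
    b <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
    yb <- y[b]
    pb <- mean(yb)
    if (pb == 0 || pb == 1) {
      # degenerate resample: stump with unit loss
      n_single_class <- n_single_class + 1L
      loss_t <- loss_matrix(1, 1)
    } else if (freeze_loss) {
      loss_t <- full_loss
    } else {
      loss_t <- loss_from_proportions(pb, multiplier = fn_multiplier)
    }
    trees[[t]] <- fit_tree(X[b, , drop = FALSE], yb, loss_t, hp)
    boot_index[[t]] <- b
    losses[[t]] <- loss_t
  }
  if (n_single_class > 0L) {
    message(n_single_class, " bootstrap sample(s) had a single outcome class; ",
            "fitted as stumps")
  }
  structure(list(trees = trees, boot_index = boot_index, loss = losses,
                 meta = list(sex = sexes, n = n, n_trees = n_trees,
                             seed = as.integer(seed), features = ids,
                             p_at_risk = p_full, full_loss = full_loss,
                             fn_multiplier = fn_multiplier,
                             freeze_loss = freeze_loss, hyperparams = hp)),
            class = "ltc_ensemble")
}

#' @export
print.ltc_ensemble <- function(x, ...) {
  cat(sprintf("<ltc_ensemble> %d trees, sex %s, n=%d, p(at risk)=%.4f\n",
              x$meta$n_trees, x$meta$sex, x$meta$n, x$meta$p_at_risk))
  invisible(x)
}

#' Extract at-risk rule paths from a fitted tree
#'
#' One rule per leaf whose predicted class is at-risk: the ordered
#' conjunction of (condition, present/absent) literals on the root-to-leaf
#' path, together with the leaf's counts on the tree's training sample.
#'
#' @param tree An `ltc_tree`.
#' @param tree_index Index recorded on each rule (bookkeeping for ensembles).
#' @return A list of rules; each rule is a list with `literals` (data frame
#'   `condition_id`, `required` in `"present"`/`"absent"`), `leaf_n`,
#'   `leaf_n_at_risk`, `leaf_id`, `tree_index`.
#' @export
extract_rules <- function(tree, tree_index = NA_integer_) {
  nd <- tree$nodes
  leaves <- which(is.na(nd$split) & nd$predicted)
  lapply(leaves, function(i) {
    lits <- list()
    j <- i
    while (!is.na(nd$parent[j])) {
      par <- nd$parent[j]
      lits[[length(lits) + 1L]] <- c(nd$split[par],
                                     if (nd$child_present[par] == nd$id[j])
                                       "present" else "absent")
      j <- par
    }
    lits <- rev(lits)
    literals <- data.frame(
      condition_id = vapply(lits, `[`, character(1), 1),
      required = vapply(lits, `[`, character(1), 2),
      stringsAsFactors = FALSE)
    list(literals = literals, leaf_n = nd$n[i], leaf_n_at_risk = nd$n_at_risk[i],
         leaf_id = nd$id[i], tree_index = tree_index)
  })
}

#' Reduce a rule path to its positive-literal condition set
#'
#' Elements of a combination requiring a negative diagnosis are disregarded:
#' only conditions required to be present are kept. An all-negative path
#' reduces to the empty set (callers discard these, with a count kept).
#'
#' @param rule A rule as returned by [extract_rules()].
#' @return Character vector of condition ids (possibly empty), in path order.
#' @export
reduce_to_positive <- function(rule) {
  lits <- rule$literals
  lits$condition_id[lits$required == "present"]
}

#' Composite scores of positive-literal condition combinations
#'
#' Collates the at-risk rules of every tree in an ensemble, reduces each to
#' its positive-literal condition set, and scores each distinct set by
#' summing, over all contributing leaves across the ensemble, the leaf's
#' probability of a correct classification (the leaf positive fraction
#' `n_at_risk / n` on that tree's bootstrap sample). The composite score thus
#' blends how often a combination appears with how accurately its leaves
#' classify. A combination met at several leaves of one tree contributes once
#' per leaf to the score but once to the count of trees in which it appears.
#'
#' @param ensemble An `ltc_ensemble`.
#' @return A data frame of class `combination_records`: `conditions` (list
#'   column of sorted condition-id vectors), `label`, `n_trees_appearing`,
#'   `n_leaves`, `composite_score`; plus attributes `n_trees` and
#'   `n_discarded` (all-negative reductions dropped).
#' @export
composite_scores <- function(ensemble) {
  n_trees <- length(ensemble$trees)
  keys <- character(0)
  env <- new.env(parent = emptyenv())
  n_discarded <- 0L
  for (t in seq_len(n_trees)) {
    rules <- extract_rules(ensemble$trees[[t]], t)
    seen_this_tree <- character(0)
    for (r in rules) {
      pos <- reduce_to_positive(r)
      if (!length(pos)) { n_discarded <- n_discarded + 1L; next }
      key <- paste(sort(pos), collapse = "+")
      contrib <- r$leaf_n_at_risk / r$leaf_n
      if (is.null(env[[key]])) {
        env[[key]] <- list(conditions = sort(pos), score = 0, trees = 0L,
                           leaves = 0L)
      }
      rec <- env[[key]]
      rec$score <- rec$score + contrib
      rec$leaves <- rec$leaves + 1L
      if (!key %in% seen_this_tree) {
        rec$trees <- rec$trees + 1L
        seen_this_tree <- c(seen_this_tree, key)
      }
      env[[key]] <- rec
    }
  }
  keys <- ls(env)
  recs <- lapply(keys, function(k) env[[k]])
  out <- data.frame(
    label = vapply(recs, function(r) combination_label(r$conditions), character(1)),
    n_trees_appearing = vapply(recs, function(r) r$trees, integer(1)),
    n_leaves = vapply(recs, function(r) r$leaves, integer(1)),
    composite_score = vapply(recs, function(r) r$score, numeric(1)),
    stringsAsFactors = FALSE)
  out$conditions <- lapply(recs, function(r) r$conditions)
  attr(out, "n_trees") <- n_trees
  attr(out, "n_discarded") <- n_discarded
  class(out) <- c("combination_records", "data.frame")
  out
}

#' Human-readable label for a condition set
#'
#' Singleton combinations are labelled "<condition> and any other LTC": in an
#' all-multimorbid cohort a single condition necessarily occurs together with
#' at least one other.
#' @noRd
combination_label <- function(conditions) {
  if (length(conditions) == 1L) {
    paste(conditions, "and any other LTC")
  } else {
    paste(conditions, collapse = " and ")
  }
}

#' Rank combinations and retain the top k
#'
#' Descending composite score; ties broken by more trees appearing in, then
#' by the lexicographic order of the condition-set key (deterministic).
#'
#' @param records `combination_records` from [composite_scores()].
#' @param k Number of combinations to retain (default 12).
#' @return The records sorted, with a `rank` column; the top `k` carry
#'   `retained = TRUE`. Attribute `k` records the cut.
#' @export
rank_and_retain <- function(records, k = 12L) {
  key <- vapply(records$conditions, paste, character(1), collapse = "+")
  ord <- order(-records$composite_score, -records$n_trees_appearing, key)
  out <- records[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  if (nrow(out) < k) {
    warning("only ", nrow(out), " combinations available; k = ", k)
  }
  out$retained <- out$rank <= k
  attr(out, "k") <- k
  attr(out, "n_trees") <- attr(records, "n_trees")
  rownames(out) <- NULL
  out
}

#' Confusion-matrix metrics of a condition combination on a cohort
#'
#' The exposure indicator is "all conditions of the set present" (for a
#' singleton in an all-multimorbid cohort this is simply the condition, the
#' "any other LTC" clause being automatic). Metrics come from the 2x2
#' exposure-by-outcome table: prevalence `P(exposed)`, positive predictive
#' value `P(at risk | exposed)`, sensitivity `P(exposed | at risk)`,
#' specificity `P(unexposed | not at risk)` and accuracy
#' `P(exposed == at risk)`, all as percentages.
#'
#' @param cohort Restricted, classified cohort (single sex for the standard
#'   analysis).
#' @param conditions Character vector of condition ids.
#' @return A one-row data frame: `prevalence_pct`, `ppv_pct`,
#'   `sensitivity_pct`, `specificity_pct`, `accuracy_pct` (PPV is `NA` when
#'   nobody is exposed).
#' @export
evaluate_combination <- function(cohort, conditions) {
  stopifnot(length(conditions) >= 1L)
  miss <- setdiff(conditions, names(cohort))
  if (length(miss)) stop("unknown condition(s): ", paste(miss, collapse = ", "))
  exposed <- rowSums(as.data.frame(cohort[conditions])) == length(conditions)
  at_risk <- cohort$at_risk
  a <- sum(exposed & at_risk); b <- sum(exposed & !at_risk)
  c_ <- sum(!exposed & at_risk); d <- sum(!exposed & !at_risk)
  n <- a + b + c_ + d
  data.frame(
    prevalence_pct = 100 * (a + b) / n,
    ppv_pct = if (a + b > 0) 100 * a / (a + b) else NA_real_,
    sensitivity_pct = 100 * a / (a + c_),
    specificity_pct = 100 * d / (b + d),
    accuracy_pct = 100 * (a + d) / n)
}

#' Ensemble-level summary of combination mining
#'
#' @param records `combination_records`.
#' @param n_trees Ensemble size (defaults to the records' attribute).
#' @return List with `n_combinations` (distinct positive-literal sets) and
#'   `n_in_half` (sets appearing in at least half of the ensemble).
#' @export
ensemble_summary <- function(records, n_trees = attr(records, "n_trees")) {
  list(n_combinations = nrow(records),
       n_in_half = sum(records$n_trees_appearing >= n_trees / 2),
       n_trees = n_trees,
       n_discarded_all_negative = attr(records, "n_discarded"))
}

#' Number of condition combinations of a given size
#'
#' `choose(n, k)`, or the cumulative sum over sizes `1..max_size`. From 53
#' conditions there are 1378 pairs, 23,426 triples, and over 10^10
#' combinations of up to ten conditions -- the combinatorial burden an
#' exhaustive regression screen would face.
#'
#' @param n_conditions Number of candidate conditions.
#' @param size Combination size.
#' @param cumulative If `TRUE`, sum over sizes 1 to `size`.
#' @return A (double) count.
#' @export
count_combinations <- function(n_conditions, size, cumulative = FALSE) {
  if (n_conditions < 0 || size < 0) stop("arguments must be non-negative")
  if (size > n_conditions) stop("size exceeds the number of conditions")
  if (cumulative) sum(choose(n_conditions, seq_len(size)))
  else choose(n_conditions, size)
}

#' Write a ranked combination table in the reporting dialect
#'
#' One row per combination: rank, label, the five confusion-matrix metrics
#' (2 decimal places), composite score and tree count.
#'
#' @param ranked Output of [rank_and_retain()].
#' @param cohort Cohort used for metric evaluation.
#' @param path Optional CSV path.
#' @param retained_only Write only the retained top-k rows.
#' @return The table (invisibly if written to file).
#' @export
combination_table <- function(ranked, cohort, path = NULL, retained_only = TRUE) {
  rows <- if (retained_only) ranked[ranked$retained, , drop = FALSE] else ranked
  metrics <- do.call(rbind, lapply(rows$conditions, function(cc) {
    evaluate_combination(cohort, cc)
  }))
  out <- cbind(data.frame(rank = rows$rank, combination = rows$label,
                          stringsAsFactors = FALSE),
               round(metrics, 2),
               data.frame(composite_score = round(rows$composite_score, 4),
                          n_trees_appearing = rows$n_trees_appearing))
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
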