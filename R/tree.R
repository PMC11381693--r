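#' Misclassification loss matrix from outcome proportions
#'
#' With a markedly imbalanced outcome, false negatives (at-risk participants
#' classified as not at risk) are penalised more heavily than false
#' positives. The penalty is derived directly from the proportions of the two
#' outcomes: `fn_penalty = (1 - p) / p` against a reference false-positive
#' cost of 1, which equalises the two classes' total expected loss at the
#' root (the altered-priors balance of standard CART).
#'
#' @param p_at_risk Proportion of at-risk cases, strictly inside (0, 1).
#' @param multiplier Extra factor on the false-negative penalty (the doubled
#'   penalty sensitivity analysis uses 2).
#' @return A list of class `loss_matrix` with `fn_penalty` and `fp_penalty`.
#' @examples
#' loss_from_proportions(0.5)$fn_penalty    # 1
#' loss_from_proportions(0.21)$fn_penalty   # 3.7619...
#' @export
loss_from_proportions <- function(p_at_risk, multiplier = 1) {
  if (!is.finite(p_at_risk) || p_at_risk <= 0 || p_at_risk >= 1) {
    stop("p_at_risk must lie strictly inside (0, 1)")
  }
  loss_matrix(fn_penalty = multiplier * (1 - p_at_risk) / p_at_risk,
              fp_penalty = 1)
}

#' @rdname loss_from_proportions
#' @param fn_penalty,fp_penalty Explicit costs (both strictly positive).
#' @export
loss_matrix <- function(fn_penalty, fp_penalty = 1) {
  if (fn_penalty <= 0 || fp_penalty <= 0) stop("penalties must be positive")
  structure(list(fn_penalty = fn_penalty, fp_penalty = fp_penalty),
            class = "loss_matrix")
}

#' Tree hyperparameters
#'
#' @param max_depth Maximum tree depth (root = depth 0).
#' @param min_node_size Minimum observations in any terminal node.
#' @param min_split Minimum observations in a node to attempt a split
#'   (default `2 * min_node_size`).
#' @param complexity_penalty Minimum weighted-Gini decrease to accept a
#'   split, as a fraction of the root's weighted impurity. The default 0 lets
#'   depth and node-size constraints govern growth; 0.01 mimics the common
#'   recursive-partitioning default for cross-checks.
#' @return A list of class `tree_hyperparams`.
#' @export
tree_hyperparams <- function(max_depth = 10L, min_node_size = 25L,
                             min_split = 2L * min_node_size,
                             complexity_penalty = 0) {
  stopifnot(max_depth >= 1L, min_node_size >= 1L,
            min_split >= 2L * min_node_size, complexity_penalty >= 0)
  structure(list(max_depth = as.integer(max_depth),
                 min_node_size = as.integer(min_node_size),
                 min_split = as.integer(min_split),
                 complexity_penalty = complexity_penalty),
            class = "tree_hyperparams")
}

#' Class-weighted Gini impurity of a binary node
#'
#' The loss matrix enters tree induction as per-observation class weights
#' (altered priors): at-risk observations carry weight `fn_penalty`, others
#' `fp_penalty`. The node impurity is `2 q (1 - q)` where `q` is the weighted
#' positive fraction.
#'
#' @param n_neg,n_pos Class counts in the node.
#' @param loss A `loss_matrix` (unit weights by default).
#' @return The impurity in `[0, 0.5]`.
#' @export
gini_impurity <- function(n_neg, n_pos, loss = loss_matrix(1, 1)) {
  if (n_neg + n_pos < 1) stop("empty node")
  w1 <- n_pos * loss$fn_penalty
  w0 <- n_neg * loss$fp_penalty
  q <- w1 / (w1 + w0)
  2 * q * (1 - q)
}

#' Fit a cost-sensitive classification tree on binary condition indicators
#'
#' Greedy top-down induction: at each node the condition maximising the
#' decrease in class-weighted Gini impurity is selected, with the loss matrix
#' applied as per-observation class weights. A split is rejected when the
#' node is smaller than `min_split`, either child would fall below
#' `min_node_size`, the depth limit is reached, the node is pure, or the best
#' decrease does not exceed `complexity_penalty` times the root's weighted
#' impurity. A condition never appears twice on a root-to-leaf path (splits on
#' binary indicators are exhausted after one use). Ties in split gain are
#' broken by the lowest column (registry) index, so fitting is fully
#' deterministic given the data. Each leaf predicts the class with minimum
#' expected misclassification loss, so a leaf predicts at-risk when its
#' positive fraction exceeds `fp_penalty / (fp_penalty + fn_penalty)`.
#'
#' @param X Integer/numeric 0-1 matrix, one column per condition (column
#'   names are condition ids).
#' @param y Logical (or 0/1) at-risk labels, length `nrow(X)`.
#' @param loss A `loss_matrix`.
#' @param hp A `tree_hyperparams`.
#' @return An object of class `ltc_tree`: a list with `nodes` (a data frame,
#'   one row per node: `id`, `depth`, `parent`, `split` (condition id or
#'   `NA`), `child_absent`, `child_present`, `n`, `n_at_risk`, `predicted`)
#'   and `meta` (training size, loss, hyperparameters, feature names).
#' @export
fit_tree <- function(X, y, loss = loss_matrix(1, 1), hp = tree_hyperparams()) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.integer(y)
  stopifnot(length(y) == nrow(X), all(y %in% c(0L, 1L)))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  p <- ncol(X)
  w <- ifelse(y == 1L, loss$fn_penalty, loss$fp_penalty)
  wy <- w * y

  # node accumulator (grown as lists, assembled into a data frame at the end)
  nodes <- list()
  add_node <- function(node) {
    nodes[[node$id]] <<- node
    node$id
  }
  node_term <- function(W1, W) if (W > 0) 2 * W1 * (W - W1) / W else 0
  root_W <- sum(w); root_W1 <- sum(wy)
  root_term <- node_term(root_W1, root_W)
  gain_floor <- hp$complexity_penalty * root_term

  next_id <- 0L
  new_id <- function() { next_id <<- next_id + 1L; next_id }

  # iterative depth-first growth
  stack <- list(list(idx = seq_len(nrow(X)), depth = 0L, parent = NA_integer_,
                     used = rep(FALSE, p), slot = NA_character_))
  while (length(stack)) {
    task <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    idx <- task$idx
    id <- new_id()
    n <- length(idx)
    n1 <- sum(y[idx])
    W <- sum(w[idx]); W1 <- sum(wy[idx])
    node <- list(id = id, depth = task$depth, parent = task$parent,
                 split = NA_character_, child_absent = NA_integer_,
                 child_present = NA_integer_, n = n, n_at_risk = n1,
                 predicted = n1 * loss$fn_penalty > (n - n1) * loss$fp_penalty)
    if (!is.na(task$parent)) {
      # wire into parent (already stored: parents are numbered before children)
      if (task$slot == "absent") nodes[[task$parent]]$child_absent <- id
      else nodes[[task$parent]]$child_present <- id
    }

    can_split <- task$depth < hp$max_depth && n >= hp$min_split &&
      n1 > 0L && n1 < n && any(!task$used)
    best_j <- 0L
    if (can_split) {
      open <- which(!task$used)
      Xi <- X[idx, open, drop = FALSE]
      cnt1 <- as.vector(crossprod(Xi, rep(1, n)))          # rows with feature
      Wj <- as.vector(crossprod(Xi, w[idx]))
      W1j <- as.vector(crossprod(Xi, wy[idx]))
      okL <- cnt1 >= hp$min_node_size
      okR <- (n - cnt1) >= hp$min_node_size
      q <- function(W1v, Wv) ifelse(Wv > 0, 2 * W1v * (Wv - W1v) / Wv, 0)
      gains <- node_term(W1, W) - q(W1j, Wj) - q(W1 - W1j, W - Wj)
      gains[!(okL & okR)] <- -Inf
      jmax <- which.max(gains)   # first maximum = lowest registry index
      if (length(jmax) && is.finite(gains[jmax]) &&
          gains[jmax] > gain_floor + 1e-12 * max(1, root_term)) {
        best_j <- open[jmax]
      }
    }
    if (best_j > 0L) {
      node$split <- colnames(X)[best_j]
      used2 <- task$used; used2[best_j] <- TRUE
      present <- X[idx, best_j] == 1
      # push present branch first so absent is processed (and numbered) first
      stack[[length(stack) + 1L]] <-
        list(idx = idx[present], depth = task$depth + 1L, parent = id,
             used = used2, slot = "present")
      stack[[length(stack) + 1L]] <-
        list(idx = idx[!present], depth = task$depth + 1L, parent = id,
             used = used2, slot = "absent")
    }
    add_node(node)
  }
  nd <- data.frame(
    id = vapply(nodes, `[[`, integer(1), "id"),
    depth = vapply(nodes, `[[`, integer(1), "depth"),
    parent = vapply(nodes, `[[`, integer(1), "parent"),
    split = vapply(nodes, `[[`, character(1), "split"),
    child_absent = vapply(nodes, `[[`, integer(1), "child_absent"),
    child_present = vapply(nodes, `[[`, integer(1), "child_present"),
    n = vapply(nodes, `[[`, integer(1), "n"),
    n_at_risk = vapply(nodes, `[[`, integer(1), "n_at_risk"),
    predicted = vapply(nodes, `[[`, logical(1), "predicted"),
    stringsAsFactors = FALSE)
  structure(list(nodes = nd,
                 meta = list(n_train = nrow(X), loss = loss, hyperparams = hp,
                             features = colnames(X))),
            class = "ltc_tree")
}

#' @export
print.ltc_tree <- function(x, ...) {
  n_leaf <- sum(is.na(x$nodes$split))
  cat(sprintf("<ltc_tree> %d nodes (%d leaves), depth %d, n_train %d\n",
              nrow(x$nodes), n_leaf, max(x$nodes$depth), x$meta$n_train))
  invisible(x)
}

#' Predict with a fitted tree
#'
#' Routes each row down the tree by its indicator values and returns the
#' predicted class and the terminal leaf id.
#'
#' @param object An `ltc_tree`.
#' @param newdata Matrix or data frame containing (at least) the training
#'   feature columns.
#' @param ... Unused.
#' @return A list with `class` (logical vector) and `leaf` (integer node
#'   ids).
#' @export
predict.ltc_tree <- function(object, newdata, ...) {
  feats <- object$meta$features
  miss <- setdiff(feats, colnames(newdata))
  if (length(miss)) stop("newdata missing columns: ", paste(miss, collapse = ", "))
  X <- as.matrix(as.data.frame(newdata)[feats])
  nd <- object$nodes
  node_of <- rep(1L, nrow(X))
  repeat {
    splits <- nd$split[node_of]
    at_internal <- !is.na(splits)
    if (!any(at_internal)) break
    rows <- which(at_internal)
    val <- X[cbind(rows, match(splits[rows], feats))]
    node_of[rows] <- ifelse(val == 1,
                            nd$child_present[node_of[rows]],
                            nd$child_absent[node_of[rows]])
  }
  list(class = nd$predicted[node_of], leaf = nd$id[node_of])
}

#' Expected misclassification loss of a tree on a dataset
#' @noRd
tree_expected_loss <- function(tree, X, y, loss = tree$meta$loss) {
  pred <- predict(tree, X)$class
  y <- as.logical(y)
  sum(ifelse(y & !pred, loss$fn_penalty, ifelse(!y & pred, loss$fp_penalty, 0)))
}

#' Serialise / restore a tree as JSON
#'
#' @param tree An `ltc_tree`.
#' @param path Optional file; when `NULL` the JSON string is returned.
#' @export
tree_to_json <- function(tree, path = NULL) {
  payload <- list(nodes = tree$nodes,
                  meta = list(n_train = tree$meta$n_train,
                              loss = unclass(tree$meta$loss),
                              hyperparams = unclass(tree$meta$hyperparams),
                              features = tree$meta$features))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' @rdname tree_to_json
#' @param json JSON string or file path produced by [tree_to_json()].
#' @export
tree_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  nodes <- as.data.frame(x$nodes, stringsAsFactors = FALSE)
  structure(list(nodes = nodes,
                 meta = list(n_train = x$meta$n_train,
                             loss = do.call(loss_matrix, as.list(x$meta$loss)),
                             hyperparams = do.call(tree_hyperparams,
                                                   as.list(x$meta$hyperparams)),
                             features = x$meta$features)),
            class = "ltc_tree")
}
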