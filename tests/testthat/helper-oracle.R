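# Independent brute-force oracle for depth-<=2 cost-sensitive trees on binary
# features. Enumerates every admissible tree structure (root split or none;
# each child split on a different feature or left as a leaf), labels leaves by
# minimum expected misclassification loss, and returns the attainable losses.
# Written directly from the definitions; shares no code with fit_tree().

leaf_loss <- function(y, fn, fp) {
  n1 <- sum(y); n0 <- length(y) - n1
  min(n1 * fn, n0 * fp)  # predict negative: lose fn per positive, and v.v.
}

enumerate_depth2_losses <- function(X, y, fn, fp, min_node = 25L,
                                    min_split = 50L) {
  n <- nrow(X); p <- ncol(X)
  losses <- leaf_loss(y, fn, fp)  # depth-0 tree
  admissible <- function(idx, j) {
    nl <- sum(X[idx, j] == 0)
    length(idx) >= min_split && nl >= min_node && (length(idx) - nl) >= min_node
  }
  child_losses <- function(idx, banned) {
    # attainable losses for a subtree over rows idx: leaf, or one split
    out <- leaf_loss(y[idx], fn, fp)
    for (g in setdiff(seq_len(p), banned)) {
      if (!admissible(idx, g)) next
      l <- idx[X[idx, g] == 0]; r <- idx[X[idx, g] == 1]
      out <- c(out, leaf_loss(y[l], fn, fp) + leaf_loss(y[r], fn, fp))
    }
    out
  }
  for (f in seq_len(p)) {
    if (!admissible(seq_len(n), f)) next
    left <- which(X[, f] == 0); right <- which(X[, f] == 1)
    ll <- child_losses(left, f)
    rl <- child_losses(right, f)
    losses <- c(losses, as.vector(outer(ll, rl, `+`)))
  }
  losses
}

# Root-level weighted Gini gains, computed from the definition (independent
# of fit_tree's vectorised path); used to decide maximiser uniqueness.
root_gini_gains <- function(X, y, fn, fp, min_node = 25L) {
  w <- ifelse(y == 1, fn, fp)
  term <- function(idx) {
    W <- sum(w[idx]); W1 <- sum(w[idx] * y[idx])
    if (W == 0) 0 else 2 * W1 * (W - W1) / W
  }
  parent <- term(seq_along(y))
  vapply(seq_len(ncol(X)), function(j) {
    l <- which(X[, j] == 0); r <- which(X[, j] == 1)
    if (length(l) < min_node || length(r) < min_node) return(-Inf)
    parent - term(l) - term(r)
  }, numeric(1))
}
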