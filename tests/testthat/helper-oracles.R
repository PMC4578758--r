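# Independent brute-force oracles used to pin down expected values.
# These deliberately re-derive quantities from first principles (exhaustive
# enumeration, direct formulas) rather than reusing package internals.

# Exhaustive weighted stump search over all features and all midpoint
# thresholds. mode = "gini" maximizes sum_k W_k^2 / W on both sides;
# mode = "sse" maximizes (sum w z)^2 / sum w on both sides. Ties broken
# toward the lowest feature index, then the lowest threshold, as the
# package documents.
oracle_stump <- function(X, y, w, mode = c("gini", "sse")) {
  mode <- match.arg(mode)
  side_score <- function(yy, ww) {
    W <- sum(ww)
    if (W <= 0) return(0)
    if (mode == "gini") {
      sum(tapply(ww, yy, sum)^2) / W
    } else {
      sum(ww * yy)^2 / W
    }
  }
  best <- list(score = side_score(y, w), feature = NA, threshold = NA)
  for (j in seq_len(ncol(X))) {
    xs <- sort(unique(X[, j]))
    if (length(xs) < 2) next
    for (t in (xs[-length(xs)] + xs[-1]) / 2) {
      L <- X[, j] <= t
      score <- side_score(y[L], w[L]) + side_score(y[!L], w[!L])
      if (score > best$score + 1e-12) {
        best <- list(score = score, feature = j, threshold = t)
      }
    }
  }
  best
}

# AUC as the explicit Mann-Whitney pair count with 1/2 credit for ties.
oracle_auc <- function(truth, score) {
  pos <- score[truth == 2]
  neg <- score[truth == 1]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(pairs)
}

# A tiny separable two-feature dataset used across the tree tests.
toy_dataset <- function() {
  tibble::tibble(
    class = c(1L, 1L, 1L, 2L, 2L),
    V1 = c(0.1, 0.3, 0.5, 0.7, 0.9),
    V2 = c(5, 4, 3, 2, 1))
}

block_cfg <- function(seed, ...) {
  sim_config(p = 1000, n_train = 50, mu2 = 0.7, rho = 0.8,
             block_size = 10, n_de = 100, n_test_per_class = 500,
             seed = seed, ...)
}
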