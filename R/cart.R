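#' Configuration for depth-capped CART base learners
#'
#' Only the depth cap regularizes the trees: the default minimum node sizes
#' allow a tree to shatter a small training set, which is exactly the
#' overfitting regime the boosting algorithms here are designed around
#' (a depth-5 tree reaches zero resubstitution error on n = 50 samples once
#' the number of variables is in the thousands). `max_depth = 1` gives a
#' decision stump, `max_depth = 5` the CART(5) learner.
#'
#' @param max_depth Maximum tree depth, between 1 and 32.
#' @param min_samples_split Minimum samples (with positive weight) a node
#'   needs to be considered for splitting.
#' @param min_samples_leaf Minimum samples on each side of a split.
#'
#' @return A `tree_config` list.
#' @examples
#' tree_config(max_depth = 1) # a stump
#' @export
tree_config <- function(max_depth = 5, min_samples_split = 2,
                        min_samples_leaf = 1) {
  if (max_depth < 1 || max_depth > 32) {
    stop("`max_depth` must be between 1 and 32", call. = FALSE)
  }
  if (min_samples_split < 2 || min_samples_leaf < 1) {
    stop("invalid minimum node sizes", call. = FALSE)
  }
  structure(list(max_depth = as.integer(max_depth),
                 min_samples_split = as.integer(min_samples_split),
                 min_samples_leaf = as.integer(min_samples_leaf)),
            class = "tree_config")
}

new_hdb_tree <- function(fit, mode, config) {
  structure(list(feature = fit$feature, threshold = fit$threshold,
                 left = fit$left, right = fit$right, value = fit$value,
                 depth = fit$depth,
                 n_variables_used = fit$n_variables_used,
                 mode = mode, config = config),
            class = "hdb_tree")
}

check_weights <- function(weights, n) {
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n) stop("`weights` has wrong length", call. = FALSE)
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("`weights` must be non-negative with positive sum", call. = FALSE)
  }
  weights
}

#' Fit a weighted classification tree
#'
#' Greedy recursive partitioning maximizing the weighted Gini impurity
#' decrease, with splits of the form `x_j <= t` and leaves labeled by the
#' weighted majority class. Thresholds are midpoints between consecutive
#' distinct sorted values; ties between candidate splits are broken toward
#' the lowest variable index, then the lowest threshold; leaf majority ties
#' go to class 1. Growth stops at `max_depth`, at the minimum node sizes,
#' or when a node is pure. If only one class is present the tree is a
#' single leaf predicting that class.
#'
#' @param data A labeled tibble (integer `class` column in `{1, 2}` plus
#'   numeric features).
#' @param weights Optional non-negative case weights (default uniform).
#'   Samples with zero weight are ignored entirely.
#' @param config A [tree_config()].
#' @param class_col Name of the label column.
#'
#' @return An object of class `hdb_tree`.
#' @examples
#' d <- simulate_null_independent(p = 5, n = 10, seed = 1)
#' tr <- fit_classification_tree(d, config = tree_config(max_depth = 2))
#' predict(tr, d)
#' @export
fit_classification_tree <- function(data, weights = NULL,
                                    config = tree_config(),
                                    class_col = "class") {
  dm <- dataset_matrix(data, class_col)
  weights <- check_weights(weights, nrow(dm$X))
  fit <- fit_tree_cpp(dm$X, as.numeric(dm$y), as.numeric(weights),
                      config$max_depth, config$min_samples_split,
                      config$min_samples_leaf, TRUE)
  new_hdb_tree(fit, "classification", config)
}

#' Fit a weighted regression tree
#'
#' Splits minimize the weighted sum of squared errors; each leaf carries
#' the weighted mean of its targets (boosting-specific leaf transforms are
#' applied by the caller). Same determinism rules as
#' [fit_classification_tree()].
#'
#' @param x Numeric feature matrix (or data frame of features).
#' @param targets Numeric response values.
#' @param weights Optional non-negative case weights (default uniform).
#' @param config A [tree_config()].
#'
#' @return An object of class `hdb_tree`.
#' @examples
#' x <- matrix(1:4, ncol = 1)
#' fit_regression_tree(x, c(-1, -1, 1, 1), config = tree_config(max_depth = 1))
#' @export
fit_regression_tree <- function(x, targets, weights = NULL,
                                config = tree_config()) {
  X <- feature_matrix(x)
  if (length(targets) != nrow(X) || any(!is.finite(targets))) {
    stop("`targets` must be finite and match `x` rows", call. = FALSE)
  }
  weights <- check_weights(weights, nrow(X))
  fit <- fit_tree_cpp(X, as.numeric(targets), as.numeric(weights),
                      config$max_depth, config$min_samples_split,
                      config$min_samples_leaf, FALSE)
  new_hdb_tree(fit, "regression", config)
}

#' Predict from a fitted tree
#'
#' Deterministic root-to-leaf routing; a sample with `x_j` exactly equal to
#' the threshold goes left.
#'
#' @param object An `hdb_tree`.
#' @param newdata A data frame (a `class` column, if present, is dropped)
#'   or numeric matrix with at least as many columns as the largest split
#'   variable index.
#' @param ... Unused.
#' @return A numeric vector: class labels (1/2) for classification trees,
#'   leaf values for regression trees.
#' @export
predict.hdb_tree <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    newdata <- newdata[setdiff(names(newdata), "class")]
  }
  X <- feature_matrix(newdata)
  used <- object$feature[object$feature > 0]
  if (length(used) && max(used) > ncol(X)) {
    stop("`newdata` has fewer columns than the tree's split variables",
         call. = FALSE)
  }
  predict_tree_cpp(object$feature, object$threshold, object$left,
                   object$right, object$value, X)
}

#' @export
print.hdb_tree <- function(x, ...) {
  cat(sprintf("<hdb_tree> %s, %d node(s), depth %d, %d variable(s) used\n",
              x$mode, length(x$feature), x$depth, x$n_variables_used))
  invisible(x)
}

#' Tidy a fitted tree into its node table
#'
#' @param x An `hdb_tree`.
#' @param ... Unused.
#' @return A tibble with one row per node: `node`, `feature` (split
#'   variable index, `NA` at leaves), `threshold`, `left`, `right` (child
#'   node ids), `value` (leaf prediction).
#' @export
tidy.hdb_tree <- function(x, ...) {
  tibble::tibble(
    node = seq_along(x$feature),
    feature = ifelse(x$feature > 0, x$feature, NA_integer_),
    threshold = x$threshold,
    left = ifelse(x$left > 0, x$left, NA_integer_),
    right = ifelse(x$right > 0, x$right, NA_integer_),
    value = x$value)
}

#' Serialize a fitted tree to JSON and back
#'
#' The node list (parent/child indices, thresholds, leaf values) round-trips
#' so that a reloaded tree predicts bit-identically.
#'
#' @param tree An `hdb_tree`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @param json A JSON string or file path produced by `tree_to_json()`.
#' @return `tree_to_json()`: the JSON string (invisibly if written to
#'   `path`); `tree_from_json()`: an `hdb_tree`.
#' @export
tree_to_json <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "hdb_tree"))
  payload <- list(
    mode = tree$mode, depth = tree$depth,
    n_variables_used = tree$n_variables_used,
    config = unclass(tree$config),
    nodes = list(feature = tree$feature, threshold = tree$threshold,
                 left = tree$left, right = tree$right, value = tree$value))
  js <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE, na = "null",
                         null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' @rdname tree_to_json
#' @export
tree_from_json <- function(json) {
  if (length(json) == 1 && file.exists(json)) json <- readLines(json)
  p <- jsonlite::fromJSON(paste(json, collapse = "\n"))
  new_hdb_tree(
    list(feature = as.integer(p$nodes$feature),
         threshold = as.numeric(p$nodes$threshold),
         left = as.integer(p$nodes$left),
         right = as.integer(p$nodes$right),
         value = as.numeric(p$nodes$value),
         depth = as.integer(p$depth),
         n_variables_used = as.integer(p$n_variables_used)),
    p$mode, do.call(tree_config, p$config))
}
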