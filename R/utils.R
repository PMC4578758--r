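# Internal helpers shared across modules. A labeled dataset is a tibble
# with an integer `class` column taking values in {1, 2} plus numeric
# feature columns.

dataset_matrix <- function(data, class_col = "class") {
  if (!is.data.frame(data)) {
    stop("`data` must be a data frame with a `", class_col, "` column",
         call. = FALSE)
  }
  if (!class_col %in% names(data)) {
    stop("column `", class_col, "` not found in `data`", call. = FALSE)
  }
  y <- as.integer(data[[class_col]])
  if (!all(y %in% c(1L, 2L))) {
    stop("class labels must take values 1 and 2", call. = FALSE)
  }
  X <- as.matrix(data[setdiff(names(data), class_col)])
  storage.mode(X) <- "double"
  list(X = X, y = y)
}

as_dataset <- function(X, y) {
  colnames(X) <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  out <- tibble::as_tibble(X)
  out <- tibble::add_column(out, class = as.integer(y), .before = 1)
  out
}

feature_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expected a numeric matrix or data frame of features", call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}

require_two_classes <- function(y) {
  if (length(unique(y)) < 2L) {
    stop("both classes must be present in the training data", call. = FALSE)
  }
  invisible(y)
}

# Stratified fold assignment: within each class, samples are permuted and
# dealt round-robin into `folds` folds, so fold sizes differ by at most one
# per class. Relies on the caller having set the RNG state.
stratified_folds <- function(y, folds) {
  fold <- integer(length(y))
  for (k in unique(y)) {
    idx <- which(y == k)
    fold[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(folds), length(idx))
  }
  fold
}

`%||%` <- function(a, b) if (is.null(a)) b else a
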