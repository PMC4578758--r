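#' Performance measures for two-class predictions
#'
#' Computes the overall predictive accuracy (PA), the class-specific
#' accuracies PA1 and PA2, the area under the ROC curve (a rank statistic
#' with midrank handling of tied scores, equivalent to the Mann-Whitney
#' probability that a class-2 sample scores above a class-1 sample), and
#' g-means, the geometric mean \eqn{\sqrt{PA_1 \cdot PA_2}}.
#'
#' @param truth True labels in `{1, 2}`.
#' @param estimate Predicted labels in `{1, 2}`.
#' @param score Optional real-valued scores, larger meaning more class-2;
#'   required for AUC.
#' @param classifier Optional classifier tag carried into the record.
#' @param m Optional iteration count carried into the record.
#'
#' @return A one-row tibble with columns `classifier`, `m`, `PA`, `PA1`,
#'   `PA2`, `AUC`, `gmeans`, `test_error` (`= 1 - PA`). With one-class
#'   truth only `PA` and `test_error` are defined; the rest are `NA`.
#' @examples
#' accuracy_metrics(c(1, 1, 2, 2), c(1, 2, 2, 2), c(.1, .6, .8, .9))
#' @export
accuracy_metrics <- function(truth, estimate, score = NULL,
                             classifier = NA_character_, m = NA_integer_) {
  stopifnot(length(truth) == length(estimate))
  truth <- as.integer(truth)
  estimate <- as.integer(estimate)
  pa <- mean(truth == estimate)
  one_class <- length(unique(truth)) < 2L
  pa1 <- if (one_class) NA_real_ else mean(estimate[truth == 1L] == 1L)
  pa2 <- if (one_class) NA_real_ else mean(estimate[truth == 2L] == 2L)
  auc <- if (one_class || is.null(score)) NA_real_ else auc_rank(truth, score)
  tibble::tibble(classifier = classifier, m = as.integer(m),
                 PA = pa, PA1 = pa1, PA2 = pa2, AUC = auc,
                 gmeans = sqrt(pa1 * pa2), test_error = 1 - pa)
}

# Midrank AUC: (mean rank of class-2 scores - (n2 + 1)/2) / n1.
auc_rank <- function(truth, score) {
  stopifnot(length(truth) == length(score))
  r <- rank(score)
  n2 <- sum(truth == 2L)
  n1 <- length(truth) - n2
  (sum(r[truth == 2L]) - n2 * (n2 + 1) / 2) / (n1 * n2)
}

#' Resubstitution error of a fitted model
#'
#' The fraction of its own training samples a classifier misclassifies.
#' For an overfitting depth-5 tree on a small high-dimensional sample this
#' is typically exactly zero even when the classes are indistinguishable,
#' which is what freezes AdaBoost.M1's weight updates.
#'
#' @param model An `hdb_tree` (classification) or `hdb_boost` object.
#' @param data The training data the model was fit on.
#' @param class_col Name of the label column.
#' @return A single error rate in `[0, 1]`.
#' @export
resubstitution_error <- function(model, data, class_col = "class") {
  y <- dataset_matrix(data, class_col)$y
  pred <- if (inherits(model, "hdb_boost")) {
    predict(model, data, type = "class")
  } else {
    predict(model, data)
  }
  mean(as.integer(pred) != y)
}

boost_fitter <- function(algorithm) {
  switch(algorithm,
         adaboost_m1 = fit_adaboost_m1,
         adaboost_m1_icv = fit_adaboost_m1_icv,
         grboost = fit_grboost,
         st_grboost = fit_st_grboost,
         logitboost = fit_logitboost,
         stop("unknown algorithm tag: ", algorithm, call. = FALSE))
}

#' Choose the number of boosting iterations by cross-validation
#'
#' The training set is split into `folds` class-stratified folds; for each
#' fold the classifier is fit with `M` iterations on the remainder and the
#' held-out samples' staged predictions are recorded. The cross-validated
#' error rate per iteration count pools the held-out predictions across
#' folds; the selected `m_cv` is the smallest iteration count attaining
#' the minimum of that curve. `folds = n` gives leave-one-out CV.
#'
#' @param data A labeled tibble.
#' @param algorithm One of `"adaboost_m1"`, `"adaboost_m1_icv"`,
#'   `"grboost"`, `"st_grboost"`, `"logitboost"`.
#' @param config A [boost_config()]; its `M` bounds the search.
#' @param folds Number of folds (`>= 2`).
#' @param seed Integer seed for the fold assignment.
#' @param class_col Name of the label column.
#'
#' @return A list of class `hdb_cv` with `m_cv` (integer) and `cv_curve`,
#'   a tibble with columns `m` and `cv_error`.
#' @examples
#' d <- simulate_null_independent(p = 5, n = 20, seed = 1)
#' sel <- select_m_by_cv(d, "grboost", boost_config(M = 5), folds = 4)
#' sel$m_cv
#' @export
select_m_by_cv <- function(data, algorithm, config = boost_config(),
                           folds = 5, seed = 1L, class_col = "class") {
  dm <- dataset_matrix(data, class_col)
  n <- length(dm$y)
  if (folds < 2 || folds > n) {
    stop("`folds` must lie between 2 and n", call. = FALSE)
  }
  fitter <- boost_fitter(algorithm)
  withr::local_seed(seed)
  fold <- if (folds == n) sample.int(n) else stratified_folds(dm$y, folds)
  miss <- matrix(NA, n, config$M) # held-out misclassification indicators
  for (f in seq_len(folds)) {
    hold <- fold == f
    fit <- fitter(data[!hold, , drop = FALSE], config,
                  class_col = class_col)
    sp <- staged_predict(fit, data[hold, , drop = FALSE])
    miss[hold, ] <- sp$class != dm$y[hold]
  }
  cv_error <- colMeans(miss)
  m_cv <- which.min(cv_error) # smallest index on ties
  structure(list(m_cv = as.integer(m_cv),
                 cv_curve = tibble::tibble(m = seq_len(config$M),
                                           cv_error = cv_error),
                 algorithm = algorithm, folds = folds),
            class = "hdb_cv")
}

#' Choose the number of boosting iterations from out-of-bag improvements
#'
#' For a stochastic gradient boosting fit, returns the iteration count
#' maximizing the cumulative sum of the per-iteration out-of-bag loss
#' improvements (the smallest such count on ties). No smoothing is applied
#' unless `smooth` is set, in which case a centered running mean of the
#' given window is taken first.
#'
#' @param model An `hdb_boost` fit with `eta < 1` (recorded out-of-bag
#'   improvements).
#' @param smooth Optional odd window width for a running-mean smoother.
#' @return An integer iteration count.
#' @export
select_m_oob <- function(model, smooth = NULL) {
  stopifnot(inherits(model, "hdb_boost"))
  if (!isTRUE(model$subsampled)) {
    stop("out-of-bag selection needs a model fit with `eta` < 1",
         call. = FALSE)
  }
  imp <- model$diagnostics$oob_improvement
  if (!is.null(smooth)) {
    k <- as.integer(smooth)
    imp <- stats::filter(imp, rep(1 / k, k), sides = 2)
    imp[is.na(imp)] <- 0
  }
  as.integer(which.max(cumsum(imp)))
}

#' Rank classifiers by g-means and compare them to a reference
#'
#' Ranks classifiers within each simulation setting by their best g-means
#' (larger is better, rank 1 best, average ranks on ties) and tests each
#' classifier against a reference with the two-sided paired Wilcoxon
#' signed-rank test across settings (exact null for up to 25 paired
#' settings, normal approximation beyond), adjusting p-values with Holm's
#' step-down method. Adjusted p-values below 0.05 are flagged significant.
#'
#' @param gmeans_by_setting A numeric matrix (rows classifiers, columns
#'   settings, rownames the classifier tags) or a tidy data frame with
#'   columns `classifier`, `setting`, `gmeans`.
#' @param reference Classifier tag to compare against.
#' @return A list with `ranks` (tibble: classifier, setting, rank) and
#'   `comparison` (tibble: classifier, statistic, p_value, p_adjusted,
#'   significant), the reference excluded from `comparison`.
#' @examples
#' g <- rbind(a = c(.8, .7, .9), b = c(.6, .5, .7), c = c(.8, .7, .9))
#' rank_and_compare(g, reference = "a")$comparison
#' @export
rank_and_compare <- function(gmeans_by_setting, reference) {
  if (is.data.frame(gmeans_by_setting)) {
    wide <- tidyr::pivot_wider(gmeans_by_setting,
                               names_from = "setting",
                               values_from = "gmeans")
    mat <- as.matrix(wide[-1])
    rownames(mat) <- wide$classifier
  } else {
    mat <- as.matrix(gmeans_by_setting)
  }
  if (nrow(mat) < 2) stop("need at least 2 classifiers", call. = FALSE)
  if (!reference %in% rownames(mat)) {
    stop("`reference` not among the classifiers", call. = FALSE)
  }
  ranks <- apply(-mat, 2, rank, ties.method = "average")
  ranks_tbl <- tibble::tibble(
    classifier = rep(rownames(mat), times = ncol(mat)),
    setting = rep(colnames(mat) %||% as.character(seq_len(ncol(mat))),
                  each = nrow(mat)),
    rank = as.vector(ranks))

  others <- setdiff(rownames(mat), reference)
  res <- purrr::map(others, function(cl) {
    d <- mat[cl, ] - mat[reference, ]
    if (all(d == 0)) {
      return(tibble::tibble(classifier = cl, statistic = NA_real_,
                            p_value = 1))
    }
    wt <- suppressWarnings(
      wilcox.test(mat[cl, ], mat[reference, ], paired = TRUE,
                  exact = ncol(mat) <= 25))
    tibble::tibble(classifier = cl,
                   statistic = unname(wt$statistic),
                   p_value = wt$p.value)
  })
  comparison <- dplyr::bind_rows(res)
  comparison$p_adjusted <- p.adjust(comparison$p_value, method = "holm")
  comparison$significant <- comparison$p_adjusted < 0.05
  list(ranks = ranks_tbl, comparison = comparison)
}

#' @export
print.hdb_cv <- function(x, ...) {
  cat(sprintf("<hdb_cv> %s, %d-fold: m_cv = %d (cv error %.4f)\n",
              x$algorithm, x$folds, x$m_cv,
              x$cv_curve$cv_error[x$m_cv]))
  invisible(x)
}

#' Tidy the cross-validation curve of an iteration selection
#'
#' @param x An `hdb_cv` object from [select_m_by_cv()].
#' @param ... Unused.
#' @return The `cv_curve` tibble (columns `m`, `cv_error`).
#' @export
tidy.hdb_cv <- function(x, ...) x$cv_curve

#' @rdname tidy.hdb_cv
#' @export
glance.hdb_cv <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm, folds = x$folds, m_cv = x$m_cv,
                 cv_error = x$cv_curve$cv_error[x$m_cv])
}
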