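#' Specify a classifier for an experiment
#'
#' @param algorithm Algorithm tag: `"cart"` for a single classification
#'   tree, or one of the boosting tags accepted by [select_m_by_cv()].
#' @param config A [boost_config()] (ignored for `"cart"` except its
#'   `tree`), or a [tree_config()] for `"cart"`.
#' @param label Display label (defaults to the tag).
#' @return A `classifier_spec` list.
#' @examples
#' classifier_spec("st_grboost", boost_config(M = 100, nu = 0.01))
#' @export
classifier_spec <- function(algorithm, config = NULL, label = algorithm) {
  structure(list(algorithm = algorithm, config = config, label = label),
            class = "classifier_spec")
}

#' Specify a replicated simulation experiment
#'
#' Couples a data-generating configuration with a set of classifiers, a
#' replicate count and the iteration grid at which staged test errors are
#' recorded. Per-replicate seeds are derived deterministically from the
#' master seed, so results are independent of evaluation order.
#'
#' @param sim A [sim_config()].
#' @param classifiers A (preferably named) list of [classifier_spec()]s.
#' @param R Number of replicates (the full-scale designs use 100).
#' @param m_grid Iteration counts at which metrics are recorded; each must
#'   be within every boosting classifier's `M`.
#' @param seed Master seed.
#' @return An `experiment_spec` list.
#' @export
experiment_spec <- function(sim, classifiers, R = 100,
                            m_grid = c(1, 10, 100, 1000), seed = 1L) {
  stopifnot(inherits(sim, "sim_config"), R >= 1)
  classifiers <- purrr::imap(classifiers, function(cl, nm) {
    stopifnot(inherits(cl, "classifier_spec"))
    if (is.character(nm) && nzchar(nm)) cl$label <- nm
    cl
  })
  structure(list(sim = sim, classifiers = classifiers, R = as.integer(R),
                 m_grid = as.integer(sort(m_grid)), seed = as.integer(seed)),
            class = "experiment_spec")
}

fit_and_score <- function(cl, train, test, m_grid, seed) {
  y_test <- dataset_matrix(test)$y
  if (cl$algorithm == "cart") {
    tree <- fit_classification_tree(
      train, config = cl$config %||% tree_config())
    pred <- predict(tree, test)
    return(accuracy_metrics(y_test, pred, classifier = cl$label, m = 1L))
  }
  config <- cl$config %||% boost_config(M = max(m_grid))
  config$seed <- seed
  grid <- m_grid[m_grid <= config$M]
  fit <- boost_fitter(cl$algorithm)(train, config)
  sp <- staged_predict(fit, test, at_iterations = grid)
  purrr::list_rbind(purrr::map(seq_along(grid), function(k) {
    accuracy_metrics(y_test, sp$class[, k], sp$score[, k],
                     classifier = cl$label, m = grid[k])
  }))
}

#' Run a replicated simulation experiment
#'
#' For each replicate a fresh training and test set is generated from the
#' replicate's derived seed, every classifier is fit on the training set,
#' and a metrics record (PA, PA1, PA2, AUC, g-means, test error) is kept
#' at every grid iteration. Replicates whose fits fail are logged and
#' skipped; more than 10 percent failures aborts the run.
#'
#' @param spec An [experiment_spec()].
#' @return A list of class `hdb_experiment` with `results` (one row per
#'   replicate x classifier x iteration count), `summary` (mean and SD per
#'   classifier x iteration count) and `n_failed`.
#' @examples
#' sp <- experiment_spec(
#'   sim_config(p = 20, n_train = 10, n_de = 5, n_test_per_class = 25),
#'   list(CART5 = classifier_spec("cart")), R = 2, m_grid = 1)
#' run_experiment(sp)$summary
#' @export
run_experiment <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  withr::local_seed(spec$seed)
  rep_seeds <- sample.int(.Machine$integer.max, spec$R)
  rows <- vector("list", spec$R)
  n_failed <- 0L
  for (r in seq_len(spec$R)) {
    sim <- spec$sim
    sim$seed <- rep_seeds[r]
    rows[[r]] <- tryCatch({
      d <- switch(sim$scenario,
                  "block-mvn" = simulate_block_mvn(sim),
                  "variance-shift" = simulate_variance_shift(
                    p_null = sim$p - 20L, seed = sim$seed,
                    n_per_class = sim$n_train %/% 2L,
                    n_test_per_class = sim$n_test_per_class),
                  stop("scenario has no train/test generator: ",
                       sim$scenario))
      out <- purrr::list_rbind(purrr::map(spec$classifiers, function(cl) {
        fit_and_score(cl, d$train, d$test, spec$m_grid, rep_seeds[r])
      }))
      out$replicate <- r
      out
    }, error = function(e) {
      message("replicate ", r, " failed: ", conditionMessage(e))
      n_failed <<- n_failed + 1L
      NULL
    })
  }
  if (n_failed > 0.1 * spec$R) {
    stop("more than 10% of replicates failed (", n_failed, "/", spec$R,
         ")", call. = FALSE)
  }
  results <- purrr::list_rbind(rows)
  summary <- results |>
    dplyr::group_by(.data$classifier, .data$m) |>
    dplyr::summarise(dplyr::across(
      c("PA", "PA1", "PA2", "AUC", "gmeans", "test_error"),
      list(mean = ~mean(.x), sd = ~sd(.x))), .groups = "drop")
  structure(list(spec = spec, results = results, summary = summary,
                 n_failed = n_failed),
            class = "hdb_experiment")
}

#' @export
print.hdb_experiment <- function(x, ...) {
  cat(sprintf("<hdb_experiment> %d replicate(s), %d classifier(s)\n",
              x$spec$R, length(x$spec$classifiers)))
  print(x$summary[c("classifier", "m", "test_error_mean",
                    "test_error_sd")])
  invisible(x)
}

#' Tidy and summarize experiment results
#'
#' @param x An `hdb_experiment`.
#' @param ... Unused.
#' @return `tidy()`: the per-replicate results tibble; `glance()`: the
#'   mean/SD summary tibble.
#' @export
tidy.hdb_experiment <- function(x, ...) x$results

#' @rdname tidy.hdb_experiment
#' @export
glance.hdb_experiment <- function(x, ...) x$summary

#' Keep the k variables with the largest sample variance
#'
#' Class-independent variance pre-filtering, the standard dimension
#' reduction applied to microarray matrices before fitting (e.g. keeping
#' the top 1000 of 22,283 probes). `k >= p` keeps everything.
#'
#' @param data A labeled tibble.
#' @param k Number of variables to retain.
#' @param class_col Name of the label column.
#' @return A labeled tibble with the surviving columns, in their original
#'   order.
#' @export
variance_prefilter <- function(data, k, class_col = "class") {
  stopifnot(k >= 1)
  vars <- setdiff(names(data), class_col)
  if (k >= length(vars)) return(data)
  v <- purrr::map_dbl(data[vars], ~var(.x, na.rm = TRUE))
  keep <- vars[order(v, decreasing = TRUE)[seq_len(k)]]
  data[c(class_col, vars[vars %in% keep])]
}

#' Drop heavily missing variables and zero-impute the rest
#'
#' Variables whose fraction of missing values strictly exceeds
#' `max_missing_fraction` are removed; remaining missing entries are
#' replaced with zeros (the convention for two-channel cDNA log-ratios,
#' where zero is the no-change value).
#'
#' @param data A labeled tibble, possibly with `NA` entries.
#' @param max_missing_fraction Threshold in `[0, 1]`; default 0.10.
#' @param class_col Name of the label column.
#' @return A labeled tibble without missing values.
#' @export
handle_missing <- function(data, max_missing_fraction = 0.10,
                           class_col = "class") {
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1)
  vars <- setdiff(names(data), class_col)
  frac <- purrr::map_dbl(data[vars], ~mean(is.na(.x)))
  keep <- vars[frac <= max_missing_fraction]
  if (length(keep) == 0) {
    stop("all variables exceed the missingness threshold", call. = FALSE)
  }
  out <- data[c(class_col, keep)]
  out[keep] <- purrr::map(out[keep], ~tidyr::replace_na(.x, 0))
  out
}

#' Balance the classes by down-sizing the majority class
#'
#' Retains a uniform without-replacement draw of `n_min` majority-class
#' samples (where `n_min` is the minority count) and all minority samples,
#' preserving the original row order of the retained samples.
#'
#' @param data A labeled tibble with both classes present.
#' @param seed Integer RNG seed.
#' @param class_col Name of the label column.
#' @return A class-balanced labeled tibble.
#' @export
downsize_majority <- function(data, seed = 1L, class_col = "class") {
  y <- dataset_matrix(data, class_col)$y
  require_two_classes(y)
  counts <- table(y)
  if (counts[1] == counts[2]) return(data)
  maj <- as.integer(names(which.max(counts)))
  withr::local_seed(seed)
  maj_idx <- which(y == maj)
  keep_maj <- sort(sample(maj_idx, min(counts)))
  data[sort(c(which(y != maj), keep_maj)), , drop = FALSE]
}

#' Repeated cross-validated evaluation with per-run down-sizing
#'
#' The evaluation harness for potentially class-imbalanced datasets:
#' within every repeat the samples are split into class-stratified folds;
#' in each CV run the training folds are balanced by down-sizing their
#' majority class before fitting, predictions on the untouched held-out
#' fold are pooled across folds, and the metrics of each repeat are
#' averaged over repeats.
#'
#' @param data A labeled tibble.
#' @param classifiers A named list of [classifier_spec()]s.
#' @param folds Number of CV folds (default 5).
#' @param repeats Number of repeated CV runs (the full-scale analyses use
#'   50).
#' @param seed Master seed.
#' @param class_col Name of the label column.
#' @return A list with `per_repeat` (tibble: repeat x classifier metrics)
#'   and `summary` (mean and SD over repeats).
#' @export
repeated_cv_evaluate <- function(data, classifiers, folds = 5, repeats = 50,
                                 seed = 1L, class_col = "class") {
  stopifnot(folds >= 2)
  dm <- dataset_matrix(data, class_col)
  n <- length(dm$y)
  withr::local_seed(seed)
  run_seeds <- sample.int(.Machine$integer.max, repeats * (folds + 1))
  dim(run_seeds) <- c(repeats, folds + 1)

  per_repeat <- purrr::list_rbind(purrr::map(seq_len(repeats), function(rp) {
    withr::local_seed(run_seeds[rp, folds + 1])
    fold <- stratified_folds(dm$y, folds)
    recs <- purrr::list_rbind(purrr::imap(classifiers, function(cl, nm) {
      pred <- integer(n)
      score <- numeric(n)
      for (f in seq_len(folds)) {
        hold <- fold == f
        train <- downsize_majority(data[!hold, , drop = FALSE],
                                   seed = run_seeds[rp, f],
                                   class_col = class_col)
        if (cl$algorithm == "cart") {
          tree <- fit_classification_tree(
            train, config = cl$config %||% tree_config(),
            class_col = class_col)
          pred[hold] <- predict(tree, data[hold, , drop = FALSE])
          score[hold] <- pred[hold]
        } else {
          config <- cl$config %||% boost_config()
          config$seed <- run_seeds[rp, f]
          fit <- boost_fitter(cl$algorithm)(train, config,
                                            class_col = class_col)
          pred[hold] <- predict(fit, data[hold, , drop = FALSE])
          score[hold] <- predict(fit, data[hold, , drop = FALSE],
                                 type = "score")
        }
      }
      out <- accuracy_metrics(dm$y, pred, score, classifier = cl$label)
      if (is.character(nm) && nzchar(nm)) out$classifier <- nm
      out$fold_assignment <- list(fold)
      out
    }))
    recs$repeat_id <- rp
    recs
  }))

  summary <- per_repeat |>
    dplyr::group_by(.data$classifier) |>
    dplyr::summarise(dplyr::across(
      c("PA", "PA1", "PA2", "AUC", "gmeans", "test_error"),
      list(mean = ~mean(.x), sd = ~sd(.x))), .groups = "drop")
  list(per_repeat = per_repeat, summary = summary)
}
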