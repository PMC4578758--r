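#' Configuration for boosting fits
#'
#' `nu`, `eta` and the base-tree configuration default per algorithm when
#' left `NULL`: gradient boosting uses `nu = 1` (no shrinkage), stochastic
#' gradient boosting `nu = 0.01` and `eta = 0.5`, LogitBoost a stump base
#' learner, and the other algorithms depth-5 trees.
#'
#' @param M Number of boosting iterations (>= 1).
#' @param nu Shrinkage factor in `(0, 1]` applied to each stage's
#'   contribution (gradient variants only).
#' @param eta Subsampling fraction in `(0, 1]`: per iteration
#'   `floor(eta * n)` samples are drawn without replacement to grow the
#'   tree (stochastic gradient boosting only).
#' @param icv_folds Folds of the internal cross-validation that replaces
#'   the resubstitution error in the AdaBoost.M1.ICV weight update.
#' @param tree A [tree_config()] for the base learners, or `NULL` for the
#'   per-algorithm default.
#' @param seed Integer seed for the algorithm's own randomness (fold
#'   assignment, subsampling). Deterministic algorithms ignore it.
#'
#' @return A `boost_config` list.
#' @examples
#' boost_config(M = 100, tree = tree_config(max_depth = 1))
#' @export
boost_config <- function(M = 100, nu = NULL, eta = NULL, icv_folds = 5,
                         tree = NULL, seed = 1L) {
  if (M < 1) stop("`M` must be at least 1", call. = FALSE)
  if (!is.null(nu) && (nu <= 0 || nu > 1)) {
    stop("`nu` must lie in (0, 1]", call. = FALSE)
  }
  if (!is.null(eta) && (eta <= 0 || eta > 1)) {
    stop("`eta` must lie in (0, 1]", call. = FALSE)
  }
  if (icv_folds < 2) stop("`icv_folds` must be at least 2", call. = FALSE)
  if (!is.null(tree)) stopifnot(inherits(tree, "tree_config"))
  structure(list(M = as.integer(M), nu = nu, eta = eta,
                 icv_folds = as.integer(icv_folds), tree = tree,
                 seed = as.integer(seed)),
            class = "boost_config")
}

GAMMA_CAP <- 8 # cap on |leaf update| under the exponential loss

new_hdb_boost <- function(algorithm, trees, config, diagnostics,
                          alphas = NULL, F0 = 0, nu = 1, extra = list()) {
  structure(c(list(algorithm = algorithm, trees = trees, alphas = alphas,
                   F0 = F0, nu = nu, config = config,
                   diagnostics = diagnostics),
              extra),
            class = c(paste0("hdb_", algorithm), "hdb_boost"))
}

resolve_tree <- function(config, default_depth) {
  config$tree %||% tree_config(max_depth = default_depth)
}

fit_tree_raw <- function(X, y, w, tc, classify) {
  fit_tree_cpp(X, as.numeric(y), as.numeric(w), tc$max_depth,
               tc$min_samples_split, tc$min_samples_leaf, classify)
}

tree_values <- function(tree, X) {
  predict_tree_cpp(tree$feature, tree$threshold, tree$left, tree$right,
                   tree$value, X)
}

tree_leaf_ids <- function(tree, X) {
  as.integer(predict_tree_cpp(tree$feature, tree$threshold, tree$left,
                              tree$right,
                              as.numeric(seq_along(tree$feature)), X))
}

# ---------------------------------------------------------------------------
# AdaBoost.M1 and AdaBoost.M1.ICV

# Stage weight alpha = ln((1 - eps)/eps). At eps = 0 the weight update is
# vacuous, so alpha is clamped at ln((1 - delta)/delta) with delta = 1/(2n)
# and the weights are left unchanged -- every later stage refits the
# identical tree and the ensemble collapses onto its base classifier (the
# mechanism behind AdaBoost.M1's failure to improve on an overfitting base
# learner). Handling of eps >= 1/2 differs per algorithm: plain AdaBoost.M1
# restarts once from uniform weights (a near-impossible edge case for the
# resubstitution error); the ICV variant applies the negative alpha as is.
adaboost_alpha <- function(eps, n) {
  if (eps <= 0) {
    delta <- 1 / (2 * n)
    log((1 - delta) / delta)
  } else {
    log((1 - eps) / eps)
  }
}

#' Fit AdaBoost.M1 with weighted classification trees
#'
#' At each iteration a weighted tree is fit, its weighted resubstitution
#' error \eqn{\epsilon_m = \sum_i w_i 1[c_m(x_i) \neq y_i]} is computed,
#' the stage weight is \eqn{\alpha_m = \ln((1-\epsilon_m)/\epsilon_m)},
#' misclassified samples have their weights multiplied by
#' \eqn{e^{\alpha_m}}, and the weights are renormalized. The final
#' prediction is the weighted majority vote
#' \eqn{\arg\max_k \sum_m \alpha_m 1[c_m(x) = k]}. When a stage reaches
#' zero resubstitution error the weights stop changing and all later
#' stages are identical, so the ensemble predicts exactly like its base
#' tree -- the regime this package exists to study.
#'
#' @param data A labeled tibble (integer `class` in `{1, 2}` plus numeric
#'   features); both classes must be present.
#' @param config A [boost_config()].
#' @param class_col Name of the label column.
#'
#' @return An object of class `hdb_boost` whose per-iteration
#'   \eqn{\epsilon_m}, \eqn{\alpha_m} are available via [tidy()].
#' @examples
#' d <- simulate_null_independent(p = 50, n = 20, seed = 1)
#' fit <- fit_adaboost_m1(d, boost_config(M = 5))
#' tidy(fit)
#' @export
fit_adaboost_m1 <- function(data, config = boost_config(),
                            class_col = "class") {
  dm <- dataset_matrix(data, class_col)
  require_two_classes(dm$y)
  tc <- resolve_tree(config, 5)
  n <- length(dm$y)
  w <- rep(1 / n, n)
  trees <- vector("list", config$M)
  eps_v <- alpha_v <- numeric(config$M)
  for (m in seq_len(config$M)) {
    tree <- fit_tree_raw(dm$X, dm$y, w, tc, TRUE)
    miss <- tree_values(tree, dm$X) != dm$y
    eps <- sum(w[miss])
    if (eps >= 0.5) { # degenerate stage: restart from uniform weights once
      w <- rep(1 / n, n)
      tree <- fit_tree_raw(dm$X, dm$y, w, tc, TRUE)
      miss <- tree_values(tree, dm$X) != dm$y
      eps <- sum(w[miss])
      if (eps >= 0.5) {
        trees[[m]] <- tree; eps_v[m] <- eps; alpha_v[m] <- 0
        next
      }
    }
    alpha <- adaboost_alpha(eps, n)
    if (eps > 0) {
      w[miss] <- w[miss] * exp(alpha)
      w <- w / sum(w)
    }
    trees[[m]] <- tree; eps_v[m] <- eps; alpha_v[m] <- alpha
  }
  new_hdb_boost("adaboost_m1", trees, config,
                tibble::tibble(m = seq_len(config$M), epsilon = eps_v,
                               alpha = alpha_v),
                alphas = alpha_v, extra = list(weights = w))
}

#' Fit AdaBoost.M1 with internally cross-validated weight updates
#'
#' Identical to [fit_adaboost_m1()] except that the error driving the
#' weight update is estimated by k-fold cross-validation inside each
#' boosting iteration: the training samples are split into `icv_folds`
#' class-stratified folds (re-randomized every iteration from the model
#' seed), a weighted tree is fit on the complement of each fold, and the
#' per-sample held-out misclassification indicators \eqn{\epsilon_m^i}
#' give \eqn{\epsilon_m = \sum_i w_i \epsilon_m^i} and the update
#' \eqn{w_i \leftarrow w_i e^{\alpha_m \epsilon_m^i}}. The stage
#' classifier voted at prediction time is refit on the full weighted
#' training set. Because the cross-validated error of an overfitting tree
#' stays well above zero, the weights keep moving and the ensemble can
#' improve on its base classifier where plain AdaBoost.M1 cannot.
#'
#' @inheritParams fit_adaboost_m1
#' @return An `hdb_boost` object.
#' @examples
#' cfg <- sim_config(p = 40, n_train = 20, n_de = 10, n_test_per_class = 20)
#' d <- simulate_block_mvn(cfg)
#' fit <- fit_adaboost_m1_icv(d$train, boost_config(M = 3, seed = 2))
#' @export
fit_adaboost_m1_icv <- function(data, config = boost_config(),
                                class_col = "class") {
  dm <- dataset_matrix(data, class_col)
  require_two_classes(dm$y)
  tc <- resolve_tree(config, 5)
  n <- length(dm$y)
  if (config$icv_folds > n %/% 2L) {
    stop("`icv_folds` too large for the training set", call. = FALSE)
  }
  withr::local_seed(config$seed)
  w <- rep(1 / n, n)
  trees <- vector("list", config$M)
  eps_v <- alpha_v <- numeric(config$M)
  first_folds <- NULL

  cv_error_indicator <- function(w) {
    fold <- stratified_folds(dm$y, config$icv_folds)
    err <- numeric(n)
    for (f in seq_len(config$icv_folds)) {
      hold <- fold == f
      ft <- fit_tree_raw(dm$X[!hold, , drop = FALSE], dm$y[!hold],
                         w[!hold], tc, TRUE)
      err[hold] <- tree_values(ft, dm$X[hold, , drop = FALSE]) !=
        dm$y[hold]
    }
    list(err = err, fold = fold)
  }

  for (m in seq_len(config$M)) {
    cv <- cv_error_indicator(w)
    if (m == 1L) first_folds <- cv$fold
    eps <- sum(w * cv$err)
    # Unlike the resubstitution error, an honest cross-validated error can
    # legitimately cross 1/2 as the weights concentrate; the unclamped
    # alpha then turns negative and pushes weight off the currently
    # misclassified samples, a self-stabilizing feedback that keeps the
    # stage trees diverse. A uniform-weight restart here would collapse
    # the ensemble onto its deterministic base tree.
    alpha <- adaboost_alpha(eps, n)
    # the stage classifier voted at prediction time is fit on the full
    # training set under the same weights the fold models saw
    trees[[m]] <- fit_tree_raw(dm$X, dm$y, w, tc, TRUE)
    w <- w * exp(alpha * cv$err)
    w <- w / sum(w)
    eps_v[m] <- eps; alpha_v[m] <- alpha
  }
  new_hdb_boost("adaboost_m1_icv", trees, config,
                tibble::tibble(m = seq_len(config$M), epsilon = eps_v,
                               alpha = alpha_v),
                alphas = alpha_v,
                extra = list(weights = w, icv_first_folds = first_folds))
}

# ---------------------------------------------------------------------------
# Gradient boosting under the exponential loss

# One gradient stage: regression tree on the pseudo-residuals, then a
# single Newton step per terminal node, gamma_j = sum(r) / sum(|r|),
# zero when the denominator vanishes and capped at |gamma| <= GAMMA_CAP.
gradient_stage <- function(X, r, tc) {
  tree <- fit_tree_raw(X, r, rep(1, length(r)), tc, FALSE)
  leaf <- tree_leaf_ids(tree, X)
  num <- rowsum(r, leaf)
  den <- rowsum(abs(r), leaf)
  gamma <- ifelse(den > 0, num / den, 0)
  gamma <- pmin(pmax(gamma, -GAMMA_CAP), GAMMA_CAP)
  tree$value[as.integer(rownames(num))] <- gamma
  tree
}

grboost_engine <- function(dm, config, eta) {
  tc <- resolve_tree(config, 5)
  nu <- config$nu %||% if (eta < 1) 0.01 else 1
  n <- length(dm$y)
  ytil <- ifelse(dm$y == 2L, 1, -1)
  n_sub <- floor(eta * n)
  if (n_sub < 2) stop("`eta` leaves fewer than 2 samples", call. = FALSE)
  F0 <- 0.5 * log(sum(dm$y == 2L) / sum(dm$y == 1L))
  Fs <- rep(F0, n)
  trees <- vector("list", config$M)
  loss_v <- numeric(config$M)
  oob_v <- rep(NA_real_, config$M)
  withr::local_seed(config$seed)
  for (m in seq_len(config$M)) {
    r <- ytil * exp(-ytil * Fs)
    if (eta < 1) {
      sub <- sample.int(n, n_sub)
      tree <- gradient_stage(dm$X[sub, , drop = FALSE], r[sub], tc)
      oob <- setdiff(seq_len(n), sub)
      before <- mean(exp(-ytil[oob] * Fs[oob]))
      Fs <- Fs + nu * tree_values(tree, dm$X)
      oob_v[m] <- before - mean(exp(-ytil[oob] * Fs[oob]))
    } else {
      tree <- gradient_stage(dm$X, r, tc)
      Fs <- Fs + nu * tree_values(tree, dm$X)
    }
    trees[[m]] <- tree
    loss_v[m] <- mean(exp(-ytil * Fs))
  }
  list(trees = trees, F0 = F0, nu = nu,
       diagnostics = tibble::tibble(m = seq_len(config$M),
                                    train_loss = loss_v,
                                    oob_improvement = oob_v))
}

#' Fit gradient boosting with the exponential loss
#'
#' Stagewise additive modeling of a real-valued score \eqn{F(x)}: classes
#' are coded \eqn{\tilde y \in \{-1, +1\}} with loss
#' \eqn{L = e^{-\tilde y F}}, the initial score is
#' \eqn{F_0 = \tfrac12 \ln(n_2/n_1)}, and each iteration fits a
#' depth-capped regression tree to the pseudo-residuals
#' \eqn{r_i = \tilde y_i e^{-\tilde y_i F(x_i)}} followed by one Newton
#' step per terminal node, \eqn{\gamma_j = \sum_{i \in R_j} r_i /
#' \sum_{i \in R_j} |r_i|}. The score update is
#' \eqn{F \leftarrow F + \nu \gamma_{j(x)}} with shrinkage `nu`
#' (default 1). Class 2 is predicted when \eqn{F > 0}; `F` is the score
#' used for AUC.
#'
#' @inheritParams fit_adaboost_m1
#' @return An `hdb_boost` object; [tidy()] exposes the per-iteration
#'   training loss.
#' @examples
#' d <- simulate_null_independent(p = 10, n = 20, seed = 1)
#' fit <- fit_grboost(d, boost_config(M = 5))
#' @export
fit_grboost <- function(data, config = boost_config(),
                        class_col = "class") {
  dm <- dataset_matrix(data, class_col)
  require_two_classes(dm$y)
  eng <- grboost_engine(dm, config, eta = 1)
  new_hdb_boost("grboost", eng$trees, config, eng$diagnostics,
                F0 = eng$F0, nu = eng$nu, extra = list(subsampled = FALSE))
}

#' Fit stochastic gradient boosting
#'
#' As [fit_grboost()], but each iteration draws `floor(eta * n)` training
#' samples without replacement (default `eta = 0.5`) and grows the tree --
#' and computes its Newton leaf updates -- on that subsample only, while
#' the score update is applied to all samples. Because the update is then
#' partly driven by samples the tree never saw, the algorithm resists the
#' base-learner overfitting that freezes AdaBoost.M1. The default
#' shrinkage is `nu = 0.01`. The mean decrease of the exponential loss on
#' the out-of-bag samples is recorded per iteration for [select_m_oob()].
#'
#' @inheritParams fit_adaboost_m1
#' @return An `hdb_boost` object.
#' @examples
#' d <- simulate_null_independent(p = 10, n = 20, seed = 1)
#' fit <- fit_st_grboost(d, boost_config(M = 5, seed = 4))
#' @export
fit_st_grboost <- function(data, config = boost_config(),
                           class_col = "class") {
  dm <- dataset_matrix(data, class_col)
  require_two_classes(dm$y)
  eta <- config$eta %||% 0.5
  eng <- grboost_engine(dm, config, eta = eta)
  new_hdb_boost("st_grboost", eng$trees, config, eng$diagnostics,
                F0 = eng$F0, nu = eng$nu,
                extra = list(subsampled = eta < 1, eta = eta))
}

#' Fit LogitBoost
#'
#' Adaptive Newton fitting of an additive logistic model: with
#' \eqn{y^* \in \{0, 1\}}, \eqn{F = 0} and \eqn{p = 1/2} initially, each
#' iteration computes working weights \eqn{w_i = p_i(1 - p_i)} (floored at
#' \eqn{2\sqrt{\epsilon}}) and working responses
#' \eqn{z_i = (y^*_i - p_i)/w_i} (clipped to \eqn{[-4, 4]}), fits a
#' weighted regression tree \eqn{f_m} to \eqn{z} (a stump by default), and
#' updates \eqn{F \leftarrow F + \tfrac12 f_m},
#' \eqn{p = 1/(1 + e^{-2F})}. Class 2 is predicted when \eqn{F > 0}; the
#' fitted probability `p` is the score.
#'
#' @inheritParams fit_adaboost_m1
#' @return An `hdb_boost` object; [tidy()] exposes the per-iteration
#'   training negative log-likelihood.
#' @examples
#' d <- simulate_null_independent(p = 10, n = 20, seed = 1)
#' fit <- fit_logitboost(d, boost_config(M = 5))
#' @export
fit_logitboost <- function(data, config = boost_config(),
                           class_col = "class") {
  dm <- dataset_matrix(data, class_col)
  require_two_classes(dm$y)
  tc <- resolve_tree(config, 1)
  n <- length(dm$y)
  z_max <- 4
  w_min <- 2 * sqrt(.Machine$double.eps)
  ystar <- as.numeric(dm$y == 2L)
  Fs <- numeric(n)
  p <- rep(0.5, n)
  trees <- vector("list", config$M)
  nll_v <- numeric(config$M)
  for (m in seq_len(config$M)) {
    w <- pmax(p * (1 - p), w_min)
    z <- pmin(pmax((ystar - p) / w, -z_max), z_max)
    tree <- fit_tree_raw(dm$X, z, w, tc, FALSE)
    Fs <- Fs + 0.5 * tree_values(tree, dm$X)
    p <- 1 / (1 + exp(-2 * Fs))
    pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    nll_v[m] <- -mean(ystar * log(pc) + (1 - ystar) * log(1 - pc))
    trees[[m]] <- tree
  }
  new_hdb_boost("logitboost", trees, config,
                tibble::tibble(m = seq_len(config$M), train_nll = nll_v))
}

# ---------------------------------------------------------------------------
# Prediction

row_cumsum <- function(S) {
  if (ncol(S) == 1L) return(S)
  t(apply(S, 1, cumsum))
}

#' Predictions from the first M' stages of a boosted model
#'
#' Evaluates the ensemble truncated to its first `M'` stages for every
#' requested `M'` in a single pass over the stages, yielding the
#' error-versus-iterations curves the evaluation procedures are built on.
#' Scores are the normalized vote margin for the AdaBoost variants, the
#' additive score `F` for the gradient variants, and the fitted
#' probability for LogitBoost.
#'
#' @param model An `hdb_boost` object.
#' @param newdata A labeled tibble, feature data frame or matrix.
#' @param at_iterations Increasing iteration counts, each `<= M` (default
#'   all of `1:M`).
#' @return A list of class `hdb_staged` with matrices `class` and `score`
#'   (rows samples, one column per requested iteration count) and the
#'   vector `iterations`.
#' @examples
#' d <- simulate_null_independent(p = 10, n = 20, seed = 1)
#' fit <- fit_grboost(d, boost_config(M = 5))
#' sp <- staged_predict(fit, d, at_iterations = c(1, 5))
#' dim(sp$class)
#' @export
staged_predict <- function(model, newdata, at_iterations = NULL) {
  stopifnot(inherits(model, "hdb_boost"))
  M <- length(model$trees)
  at_iterations <- as.integer(at_iterations %||% seq_len(M))
  if (any(at_iterations < 1L) || any(at_iterations > M)) {
    stop("`at_iterations` must lie in 1..M", call. = FALSE)
  }
  if (is.data.frame(newdata)) {
    newdata <- newdata[setdiff(names(newdata), "class")]
  }
  X <- feature_matrix(newdata)
  S <- predict_stages_cpp(model$trees, X)

  if (model$algorithm %in% c("adaboost_m1", "adaboost_m1_icv")) {
    sgn <- ifelse(S == 2, 1, -1)
    margin <- row_cumsum(sweep(sgn, 2, model$alphas, `*`))
    asum <- cumsum(model$alphas)
    score <- sweep(margin, 2, ifelse(asum > 0, asum, 1), `/`)
    score <- score[, at_iterations, drop = FALSE]
    cls <- ifelse(margin[, at_iterations, drop = FALSE] > 0, 2L, 1L)
  } else {
    Fm <- model$F0 + model$nu * row_cumsum(S)
    if (model$algorithm == "logitboost") {
      # stages store raw f_m; F adds f_m / 2 and the score is p
      Fm <- Fm / 2
      score <- 1 / (1 + exp(-2 * Fm[, at_iterations, drop = FALSE]))
    } else {
      score <- Fm[, at_iterations, drop = FALSE]
    }
    cls <- ifelse(Fm[, at_iterations, drop = FALSE] > 0, 2L, 1L)
  }
  structure(list(class = cls, score = score, iterations = at_iterations),
            class = "hdb_staged")
}

#' Predict classes or scores from a boosted model
#'
#' @param object An `hdb_boost` object.
#' @param newdata A labeled tibble, feature data frame or matrix.
#' @param type `"class"` for labels in `{1, 2}`, `"score"` for the
#'   ensemble score (vote margin, additive score or probability).
#' @param m Number of stages to use (default all).
#' @param ... Unused.
#' @return A vector of length `nrow(newdata)`.
#' @export
predict.hdb_boost <- function(object, newdata,
                              type = c("class", "score"), m = NULL, ...) {
  type <- match.arg(type)
  m <- as.integer(m %||% length(object$trees))
  sp <- staged_predict(object, newdata, at_iterations = m)
  if (type == "class") as.integer(sp$class[, 1L]) else sp$score[, 1L]
}

#' Staged test-set error curve
#'
#' @param model An `hdb_boost` object.
#' @param data A labeled tibble.
#' @param at_iterations Iteration counts (default `1:M`).
#' @param class_col Name of the label column.
#' @return A tibble with columns `m` and `error`.
#' @export
staged_errors <- function(model, data, at_iterations = NULL,
                          class_col = "class") {
  y <- dataset_matrix(data, class_col)$y
  sp <- staged_predict(model, data, at_iterations)
  tibble::tibble(m = sp$iterations,
                 error = colMeans(sp$class != y))
}

#' @export
print.hdb_boost <- function(x, ...) {
  cat(sprintf("<hdb_boost> %s, %d stage(s)\n", x$algorithm,
              length(x$trees)))
  invisible(x)
}

#' Tidy per-iteration diagnostics of a boosted model
#'
#' @param x An `hdb_boost` object.
#' @param ... Unused.
#' @return A tibble with one row per boosting iteration: stage error and
#'   weight (`epsilon`, `alpha`) for the AdaBoost variants, training
#'   exponential loss and out-of-bag improvement for the gradient
#'   variants, training negative log-likelihood for LogitBoost.
#' @export
tidy.hdb_boost <- function(x, ...) x$diagnostics

#' One-row summary of a boosted model
#'
#' @param x An `hdb_boost` object.
#' @param ... Unused.
#' @return A one-row tibble with the algorithm tag and hyperparameters.
#' @export
glance.hdb_boost <- function(x, ...) {
  tc <- x$config$tree %||%
    tree_config(max_depth = if (x$algorithm == "logitboost") 1 else 5)
  tibble::tibble(algorithm = x$algorithm, M = length(x$trees),
                 nu = x$nu %||% NA_real_,
                 eta = x$eta %||% NA_real_,
                 max_depth = tc$max_depth,
                 F0 = x$F0 %||% NA_real_)
}

#' Serialize a boosted model to JSON and back
#'
#' Stages, stage weights, the initial score and the configuration are
#' stored at full precision, so a reloaded model predicts bit-identically.
#'
#' @param model An `hdb_boost` object.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @param json A JSON string or file path written by `boost_to_json()`.
#' @return `boost_to_json()`: the JSON string (invisibly if written);
#'   `boost_from_json()`: an `hdb_boost` object.
#' @export
boost_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "hdb_boost"))
  cfg <- unclass(model$config)
  cfg$tree <- if (is.null(cfg$tree)) NULL else unclass(cfg$tree)
  payload <- list(
    algorithm = model$algorithm,
    alphas = model$alphas, F0 = model$F0, nu = model$nu,
    eta = model$eta, subsampled = model$subsampled,
    config = cfg,
    stages = lapply(model$trees, function(t) {
      t[c("feature", "threshold", "left", "right", "value")]
    }))
  js <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE, na = "null",
                         null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' @rdname boost_to_json
#' @export
boost_from_json <- function(json) {
  if (length(json) == 1 && file.exists(json)) json <- readLines(json)
  p <- jsonlite::fromJSON(paste(json, collapse = "\n"),
                          simplifyDataFrame = FALSE)
  cfg <- p$config
  cfg$tree <- if (is.null(cfg$tree)) NULL else do.call(tree_config, cfg$tree)
  config <- do.call(boost_config, cfg)
  trees <- lapply(p$stages, function(t) {
    list(feature = as.integer(t$feature),
         threshold = as.numeric(unlist(t$threshold)),
         left = as.integer(t$left), right = as.integer(t$right),
         value = as.numeric(t$value))
  })
  new_hdb_boost(p$algorithm, trees, config,
                tibble::tibble(m = seq_along(trees)),
                alphas = if (is.null(p$alphas)) NULL
                         else as.numeric(p$alphas),
                F0 = p$F0 %||% 0, nu = p$nu %||% 1,
                extra = list(subsampled = isTRUE(p$subsampled),
                             eta = p$eta))
}
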