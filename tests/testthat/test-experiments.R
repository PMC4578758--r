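test_that("variance pre-filtering keeps exactly the top-k variance columns", {
  withr::local_seed(101)
  X <- matrix(rnorm(60 * 50), 60, 50)
  planted <- sample(50, 8)
  X[, planted] <- X[, planted] * 10
  d <- hdboost:::as_dataset(X, rep(1:2, each = 30))
  out <- variance_prefilter(d, k = 8)
  expect_equal(sort(setdiff(names(out), "class")),
               sort(paste0("V", sort(planted))))
  # the survivors are the sort-by-variance oracle's choice
  v <- apply(X, 2, var)
  expect_setequal(setdiff(names(out), "class"),
                  paste0("V", order(v, decreasing = TRUE)[1:8]))
  expect_identical(variance_prefilter(d, k = 50), d)
  expect_identical(variance_prefilter(d, k = 1000), d)
})

test_that("missing-value handling drops >10% columns and zero-imputes the rest", {
  d <- tibble::tibble(class = rep(1:2, each = 50),
                      V1 = rnorm(100), V2 = rnorm(100), V3 = rnorm(100))
  d$V1[1:11] <- NA # 11% missing: dropped
  d$V2[1:10] <- NA # exactly 10%: retained, imputed with zeros
  out <- handle_missing(d)
  expect_equal(setdiff(names(out), "class"), c("V2", "V3"))
  expect_equal(out$V2[1:10], rep(0, 10))
  expect_false(anyNA(out))

  clean <- tibble::tibble(class = c(1L, 2L), V1 = c(1, 2))
  expect_identical(handle_missing(clean), clean)
  allna <- tibble::tibble(class = rep(1:2, 5), V1 = rep(NA_real_, 10))
  expect_error(handle_missing(allna), "threshold")
})

test_that("down-sizing the majority class balances the data uniformly", {
  d <- make_imbalanced_fixture(34, 211, p = 5, seed = 1)
  out <- downsize_majority(d, seed = 9)
  expect_equal(unname(table(out$class)), c(34L, 34L), ignore_attr = TRUE)

  balanced <- make_imbalanced_fixture(10, 10, p = 3, seed = 2)
  expect_identical(downsize_majority(balanced, seed = 1), balanced)

  # inclusion frequencies on a 5-sample majority are uniform
  toy <- tibble::tibble(class = c(1L, 1L, rep(2L, 5)),
                        V1 = as.numeric(1:7))
  counts <- numeric(5)
  for (s in 1:4000) {
    kept <- downsize_majority(toy, seed = s)$V1
    kept <- kept[kept > 2] - 2
    counts[kept] <- counts[kept] + 1
  }
  # each majority sample should be kept in ~2/5 of draws
  expect_equal(counts / 4000, rep(0.4, 5), tolerance = 0.05)
})

test_that("experiment runs are deterministic and summaries recompute exactly", {
  spec <- experiment_spec(
    sim_config(p = 40, n_train = 16, mu2 = 1, n_de = 10,
               n_test_per_class = 30),
    list(CART5 = classifier_spec("cart"),
         GrBoost5 = classifier_spec("grboost", boost_config(M = 5))),
    R = 3, m_grid = c(1, 5), seed = 7)
  ex1 <- run_experiment(spec)
  ex2 <- run_experiment(spec)
  expect_identical(tidy(ex1), tidy(ex2))

  res <- tidy(ex1)
  expect_equal(nrow(res), 3 * (1 + 2)) # cart once, grboost at two Ms
  cart_mean <- mean(res$test_error[res$classifier == "CART5"])
  expect_equal(
    glance(ex1)$test_error_mean[glance(ex1)$classifier == "CART5"],
    cart_mean)
  # per-replicate rows round-trip through delimited text bit-exactly
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(res, f)
  back <- readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
  expect_equal(nrow(back), nrow(res))
  expect_identical(back$test_error, res$test_error)
  expect_identical(back$AUC, res$AUC)
  expect_identical(back$gmeans, res$gmeans)
})

test_that("AdaBoost.M1(5) freezes in the flagship design while ICV keeps moving", {
  # p = 1000, n = 50, mu2 = 0.7: the depth-5 stages all reach zero
  # resubstitution error, so AdaBoost.M1's staged errors are constant in
  # M to machine precision, while the cross-validated error estimate
  # stays positive and keeps the ICV weights updating
  spec <- experiment_spec(
    block_cfg(seed = 1),
    list(AdaBoostM1_5 = classifier_spec("adaboost_m1",
                                        boost_config(M = 300))),
    R = 3, m_grid = c(1, 100, 300), seed = 13)
  res <- tidy(run_experiment(spec))
  for (r in unique(res$replicate)) {
    err <- res$test_error[res$replicate == r]
    expect_equal(err[2], err[1], tolerance = 1e-12)
    expect_equal(err[3], err[1], tolerance = 1e-12)
  }

  d <- simulate_block_mvn(block_cfg(seed = 2))
  icv <- fit_adaboost_m1_icv(d$train, boost_config(M = 60, seed = 2))
  dg <- tidy(icv)
  expect_true(all(dg$epsilon > 0))
  expect_gt(length(unique(round(dg$alpha, 10))), 10)
  expect_false(isTRUE(all.equal(icv$weights, rep(1 / 50, 50))))
  # the staged predictions actually change across iterations
  sp <- staged_predict(icv, d$test, at_iterations = c(1, 60))
  expect_gt(mean(sp$class[, 1] != sp$class[, 2]), 0)
})

test_that("ICV boosting improves on its base tree and gains from many iterations", {
  # reduced-scale Monte-Carlo check (5 replicates) of the flagship
  # comparison; the full-scale design averages 100 replicates
  errs <- sapply(1:5, function(r) {
    d <- simulate_block_mvn(block_cfg(seed = 500 + r))
    fit <- fit_adaboost_m1_icv(d$train,
                               boost_config(M = 1000, seed = 500 + r))
    se <- staged_errors(fit, d$test, at_iterations = c(1, 100, 1000))
    se$error
  })
  # improves on the base classifier (= its own M = 1 stage) on average
  expect_gt(mean(errs[1, ] - errs[3, ]), 0)
  # robust to large M: iterations beyond 100 still help on average
  expect_gt(mean(errs[2, ] - errs[3, ]), 0)
})

test_that("LogitBoost reaches its optimum early and never improves late", {
  # the overfitting signature: the staged test error dips well before the
  # iteration budget is spent and the late curve shows no new minima
  stats <- sapply(1:3, function(r) {
    d <- simulate_block_mvn(block_cfg(seed = 200 + r))
    fit <- fit_logitboost(d$train, boost_config(M = 1000))
    err <- staged_errors(fit, d$test)$error
    c(argmin = which.min(err), gap = err[1000] - min(err),
      late_gain = min(err[1:500]) - min(err[501:1000]))
  })
  expect_lt(mean(stats["argmin", ]), 500)
  expect_gte(min(stats["gap", ]), 0)
  expect_gt(mean(stats["gap", ]), 0)
  # no material late improvement: the second half of the curve never
  # undercuts the first half by more than a few test-set steps (1/1000)
  expect_lt(max(stats["late_gain", ]), 0.01)
})

test_that("repeated CV partitions samples and is reproducible", {
  withr::local_seed(107)
  d <- tibble::tibble(class = rep(1:2, times = c(12, 20)),
                      V1 = c(rnorm(12), rnorm(20) + 8),
                      V2 = rnorm(32))
  out <- repeated_cv_evaluate(
    d, list(CART5 = classifier_spec("cart")), folds = 4, repeats = 2,
    seed = 5)
  expect_equal(nrow(out$per_repeat), 2L)
  for (fold in out$per_repeat$fold_assignment) {
    expect_equal(sort(unique(fold)), 1:4)
    expect_length(fold, 32)
  }
  out2 <- repeated_cv_evaluate(
    d, list(CART5 = classifier_spec("cart")), folds = 4, repeats = 2,
    seed = 5)
  expect_equal(out$summary, out2$summary)
  # deterministic classifier on separable data: perfect g-means, zero SD
  expect_equal(out$summary$gmeans_mean, 1)
  expect_equal(out$summary$gmeans_sd, 0)
})
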