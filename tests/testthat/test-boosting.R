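test_that("one AdaBoost.M1 iteration reproduces the hand-computed update", {
  # stump cannot separate sample 2: epsilon = 1/4, alpha = ln 3, and the
  # misclassified weight renormalizes to 1/2
  d <- tibble::tibble(class = c(1L, 2L, 1L, 1L), V1 = c(1, 2, 3, 4))
  fit <- fit_adaboost_m1(d, boost_config(M = 1,
                                         tree = tree_config(max_depth = 1)))
  diag1 <- tidy(fit)
  expect_equal(diag1$epsilon, 0.25)
  expect_equal(diag1$alpha, log(3))
  expect_equal(fit$weights, c(1, 3, 1, 1) / 6)
  expect_equal(fit$weights[2], 0.5)
})

test_that("zero training error freezes AdaBoost.M1 onto its base tree", {
  d <- simulate_null_independent(p = 2000, n = 30, seed = 2)
  fit <- fit_adaboost_m1(d, boost_config(M = 8))
  expect_true(all(tidy(fit)$epsilon == 0))
  expect_equal(tidy(fit)$alpha,
               rep(log((1 - 1 / 60) / (1 / 60)), 8))
  base <- fit_classification_tree(d)
  probe <- simulate_null_independent(p = 2000, n = 100, seed = 99)
  sp <- staged_predict(fit, probe)
  for (m in seq_len(8)) {
    expect_identical(as.integer(sp$class[, m]),
                     as.integer(predict(base, probe)))
  }
})

test_that("AdaBoost weights stay normalized and correct samples never gain", {
  cfg <- sim_config(p = 20, n_train = 30, mu2 = 1, block_size = 10,
                    n_de = 10, n_test_per_class = 10, seed = 31)
  d <- simulate_block_mvn(cfg)$train
  fit <- fit_adaboost_m1(d, boost_config(
    M = 15, tree = tree_config(max_depth = 1)))
  dg <- tidy(fit)
  expect_equal(sum(fit$weights), 1)
  expect_true(all(dg$epsilon >= 0 & dg$epsilon < 0.5))
  expect_true(all(dg$alpha >= 0))
})

test_that("one ICV iteration matches a step-by-step manual recomputation", {
  cfg <- sim_config(p = 10, n_train = 20, mu2 = 1.5, block_size = 10,
                    n_de = 10, n_test_per_class = 10, seed = 17)
  d <- simulate_block_mvn(cfg)$train
  n <- nrow(d)
  fit <- fit_adaboost_m1_icv(d, boost_config(M = 1, seed = 23))
  fold <- fit$icv_first_folds

  # manual execution of the recursion on the recorded folds
  w <- rep(1 / n, n)
  err <- numeric(n)
  for (f in sort(unique(fold))) {
    hold <- fold == f
    ft <- fit_classification_tree(d[!hold, ], weights = w[!hold])
    err[hold] <- predict(ft, d[hold, ]) != d$class[hold]
  }
  eps <- sum(w * err)
  expect_lt(eps, 0.5) # this fixture avoids the restart branch
  alpha <- if (eps == 0) log((2 * n - 1)) else log((1 - eps) / eps)
  w2 <- w * exp(alpha * err)
  w2 <- w2 / sum(w2)

  expect_equal(tidy(fit)$epsilon, eps)
  expect_equal(tidy(fit)$alpha, alpha)
  expect_equal(fit$weights, w2)
  # the voted stage tree is the full-data fit under the pre-update weights
  stage <- fit_classification_tree(d, weights = w)
  expect_equal(fit$trees[[1]]$threshold, stage$threshold)
})

test_that("perfectly cross-validation-predictable data never update ICV weights", {
  # wide class separation: every held-out sample is classified correctly
  withr::local_seed(61)
  d <- tibble::tibble(class = rep(1:2, each = 10),
                      V1 = c(rnorm(10), rnorm(10) + 50))
  fit <- fit_adaboost_m1_icv(d, boost_config(M = 4, seed = 5))
  expect_true(all(tidy(fit)$epsilon == 0))
  expect_equal(fit$weights, rep(1 / 20, 20))
  sp <- staged_predict(fit, d)
  base <- fit_classification_tree(d)
  for (m in 1:4) {
    expect_identical(as.integer(sp$class[, m]),
                     as.integer(predict(base, d)))
  }
})

test_that("the exponential-loss Newton leaf update is sum(r)/sum(|r|)", {
  X <- matrix(1, 3, 1) # constant feature: the stage is a single leaf
  tree <- hdboost:::gradient_stage(X, c(1, -1, 1), tree_config())
  expect_equal(length(tree$feature), 1L)
  expect_equal(tree$value, 1 / 3)
})

test_that("gradient boosting starts at the log-odds and reduces training loss", {
  d <- make_imbalanced_fixture(8, 16, p = 5, seed = 3)
  fit <- fit_grboost(d, boost_config(M = 10))
  expect_equal(fit$F0, 0.5 * log(2))
  expect_true(all(diff(tidy(fit)$train_loss) <= 1e-10))

  # vanishing shrinkage: predictions collapse to the majority class
  fit0 <- fit_grboost(d, boost_config(M = 1, nu = 1e-4))
  expect_true(all(predict(fit0, d) == 2L))
})

test_that("subsampling with eta = 1 reproduces gradient boosting stage-for-stage", {
  cfg <- sim_config(p = 50, n_train = 30, mu2 = 0.7, n_de = 10,
                    n_test_per_class = 30, seed = 41)
  d <- simulate_block_mvn(cfg)
  f1 <- fit_grboost(d$train, boost_config(M = 15, seed = 7))
  f2 <- fit_st_grboost(d$train, boost_config(M = 15, eta = 1, nu = 1,
                                             seed = 7))
  for (m in 1:15) {
    expect_equal(f2$trees[[m]], f1$trees[[m]])
  }
  expect_identical(staged_predict(f2, d$test)$score,
                   staged_predict(f1, d$test)$score)
})

test_that("stochastic gradient boosting subsamples floor(eta * n) without replacement", {
  d <- simulate_null_independent(p = 1000, n = 50, seed = 12)
  # depth-5 tree on 25 of 50 null samples: the tree can overfit its
  # subsample but the out-of-bag improvements stay recorded
  fit <- fit_st_grboost(d, boost_config(M = 10, seed = 9))
  expect_equal(fit$eta, 0.5)
  expect_equal(fit$nu, 0.01)
  expect_true(all(is.finite(tidy(fit)$oob_improvement)))
  expect_error(fit_st_grboost(d, boost_config(M = 2, eta = 0.02)),
               "fewer than 2")
})

test_that("LogitBoost's first iteration has z = +/-2 and w = 1/4", {
  d <- toy_dataset()
  ystar <- as.numeric(d$class == 2)
  # from p = 1/2: w_i = 1/4 and z_i = 4 (y* - 1/2) = +/-2, so the first
  # stage equals a weighted LS stump on z with uniform weights
  stump <- fit_regression_tree(as.matrix(d[-1]), 4 * (ystar - 0.5),
                               weights = rep(0.25, 5),
                               config = tree_config(max_depth = 1))
  fit <- fit_logitboost(d, boost_config(M = 1))
  expect_equal(fit$trees[[1]]$threshold, stump$threshold)
  expect_equal(fit$trees[[1]]$value, stump$value)
  ref <- oracle_stump(as.matrix(d[-1]), 4 * (ystar - 0.5), rep(0.25, 5),
                      mode = "sse")
  expect_equal(tidy(stump)$feature[1], ref$feature)
  expect_equal(tidy(stump)$threshold[1], ref$threshold)
})

test_that("LogitBoost training log-likelihood improves on separable data", {
  d <- tibble::tibble(class = rep(1:2, each = 6),
                      V1 = c(1:6, 11:16) + 0)
  fit <- fit_logitboost(d, boost_config(M = 5))
  nll <- tidy(fit)$train_nll
  expect_lt(nll[5], nll[1])
  expect_equal(predict(fit, d), d$class)
})

test_that("staged predictions equal full refits truncated at each M'", {
  cfg <- sim_config(p = 30, n_train = 20, mu2 = 1, n_de = 10,
                    n_test_per_class = 25, seed = 19)
  d <- simulate_block_mvn(cfg)
  full <- fit_grboost(d$train, boost_config(M = 6))
  sp <- staged_predict(full, d$test)
  expect_equal(sp$iterations, 1:6)
  for (mp in c(1, 3, 6)) {
    refit <- fit_grboost(d$train, boost_config(M = mp))
    expect_equal(predict(refit, d$test, type = "score"),
                 unname(sp$score[, mp]))
    expect_identical(as.integer(predict(refit, d$test)),
                     as.integer(sp$class[, mp]))
  }
  expect_error(staged_predict(full, d$test, at_iterations = 7), "1..M")
  # M' = M reproduces the full model
  expect_identical(predict(full, d$test),
                   as.integer(sp$class[, 6]))
})

test_that("boosted models round-trip through JSON with identical predictions", {
  cfg <- sim_config(p = 20, n_train = 20, mu2 = 1, n_de = 10,
                    n_test_per_class = 20, seed = 29)
  d <- simulate_block_mvn(cfg)
  for (fitter in list(fit_adaboost_m1, fit_grboost, fit_logitboost)) {
    fit <- fitter(d$train, boost_config(M = 4, seed = 2))
    f <- withr::local_tempfile(fileext = ".json")
    boost_to_json(fit, f)
    fit2 <- boost_from_json(f)
    expect_identical(predict(fit2, d$test), predict(fit, d$test))
    expect_identical(predict(fit2, d$test, type = "score"),
                     predict(fit, d$test, type = "score"))
  }
})

test_that("fits are reproducible under a fixed seed and reject bad input", {
  cfg <- sim_config(p = 20, n_train = 20, mu2 = 0.7, n_de = 10,
                    n_test_per_class = 10, seed = 37)
  d <- simulate_block_mvn(cfg)$train
  f1 <- fit_st_grboost(d, boost_config(M = 5, seed = 11))
  f2 <- fit_st_grboost(d, boost_config(M = 5, seed = 11))
  expect_equal(f1$trees, f2$trees)
  i1 <- fit_adaboost_m1_icv(d, boost_config(M = 3, seed = 13))
  i2 <- fit_adaboost_m1_icv(d, boost_config(M = 3, seed = 13))
  expect_equal(i1$trees, i2$trees)

  one_class <- tibble::tibble(class = rep(1L, 6), V1 = rnorm(6))
  expect_error(fit_adaboost_m1(one_class), "both classes")
  expect_error(boost_config(M = 0), "at least 1")
  expect_error(
    fit_adaboost_m1_icv(d[c(1:3, 11:13), ], boost_config(icv_folds = 5)),
    "folds")
})
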