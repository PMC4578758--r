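#' Simulation configuration for synthetic two-class data
#'
#' Bundles the parameters of the data-generating processes used throughout
#' the package: block-correlated multivariate normal data with a mean shift
#' on the differentially expressed (DE) variables, independent null data,
#' and a variance-shift design where the classes differ only in spread.
#'
#' @param p Number of variables.
#' @param n_train Training-set size; must be even (classes are balanced).
#' @param mu2 Mean of the DE variables in class 2 (class 1 means are all 0).
#' @param rho Within-block exchangeable correlation, in `[0, 1)`.
#' @param block_size Number of consecutive variables per correlated block;
#'   must divide `p` in the block-correlated scenario.
#' @param n_de Number of differentially expressed variables (the first
#'   `n_de` columns); must not exceed `p`.
#' @param n_test_per_class Test samples drawn per class.
#' @param scenario One of `"block-mvn"`, `"null-independent"`,
#'   `"variance-shift"`.
#' @param seed Integer RNG seed.
#'
#' @return A `sim_config` list.
#' @examples
#' cfg <- sim_config(p = 100, n_train = 20, n_de = 10, seed = 1)
#' @export
sim_config <- function(p = 1000, n_train = 50, mu2 = 0.7, rho = 0.8,
                       block_size = 10, n_de = 100, n_test_per_class = 500,
                       scenario = c("block-mvn", "null-independent",
                                    "variance-shift"),
                       seed = 1L) {
  scenario <- match.arg(scenario)
  if (n_de > p) stop("`n_de` must not exceed `p`", call. = FALSE)
  if (rho < 0 || rho >= 1) stop("`rho` must lie in [0, 1)", call. = FALSE)
  if (n_train %% 2L != 0L) {
    stop("`n_train` must be even (balanced classes)", call. = FALSE)
  }
  if (scenario == "block-mvn" && p %% block_size != 0L) {
    stop("`block_size` must divide `p`", call. = FALSE)
  }
  structure(
    list(p = as.integer(p), n_train = as.integer(n_train), mu2 = mu2,
         rho = rho, block_size = as.integer(block_size),
         n_de = as.integer(n_de),
         n_test_per_class = as.integer(n_test_per_class),
         scenario = scenario, seed = as.integer(seed)),
    class = "sim_config")
}

# Draw n samples of p block-correlated standard normal variables.
# Exchangeable correlation rho within consecutive blocks, independence
# across blocks, realized through the Cholesky factor of one block
# (O(n * p) memory, no p x p matrix).
block_mvn_draw <- function(n, p, rho, block_size) {
  Z <- matrix(rnorm(n * p), nrow = n, ncol = p)
  if (rho > 0) {
    S <- matrix(rho, block_size, block_size)
    diag(S) <- 1
    R <- chol(S)
    for (b in seq_len(p / block_size)) {
      cols <- ((b - 1L) * block_size + 1L):(b * block_size)
      Z[, cols] <- Z[, cols] %*% R
    }
  }
  Z
}

# One balanced draw: class 1 rows first, then class 2 with the mean shift.
block_mvn_dataset <- function(n_per_class, config) {
  X1 <- block_mvn_draw(n_per_class, config$p, config$rho, config$block_size)
  X2 <- block_mvn_draw(n_per_class, config$p, config$rho, config$block_size)
  if (config$n_de > 0) {
    X2[, seq_len(config$n_de)] <- X2[, seq_len(config$n_de)] + config$mu2
  }
  as_dataset(rbind(X1, X2), rep(1:2, each = n_per_class))
}

#' Simulate block-correlated multivariate normal training and test data
#'
#' Class 1 has mean zero everywhere; class 2 has mean `mu2` on the first
#' `n_de` variables and zero elsewhere. All variances are 1; variables
#' within a block of `block_size` consecutive columns share exchangeable
#' correlation `rho`, variables in different blocks are independent. The
#' training set is balanced; the test set holds `n_test_per_class` samples
#' per class and is drawn from the same RNG stream after the training set.
#'
#' @param config A [sim_config()] with `scenario = "block-mvn"`.
#' @return A list with tibbles `train` and `test`.
#' @examples
#' d <- simulate_block_mvn(sim_config(p = 50, n_train = 10, n_de = 10,
#'                                    n_test_per_class = 20, seed = 7))
#' table(d$train$class)
#' @export
simulate_block_mvn <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$scenario != "block-mvn") {
    stop("`config$scenario` must be \"block-mvn\"", call. = FALSE)
  }
  withr::local_seed(config$seed)
  list(train = block_mvn_dataset(config$n_train %/% 2L, config),
       test = block_mvn_dataset(config$n_test_per_class, config))
}

#' Simulate independent null data with uninformative labels
#'
#' All variables are iid standard normal in both classes, so the Bayes
#' error is 0.5. Used to study overfitting of the base trees: with enough
#' variables a depth-5 tree separates any small sample perfectly.
#'
#' @param p Number of variables.
#' @param n Number of samples; must be even (half per class).
#' @param seed Integer RNG seed.
#' @return A labeled tibble.
#' @examples
#' d <- simulate_null_independent(p = 20, n = 10, seed = 3)
#' @export
simulate_null_independent <- function(p, n, seed) {
  if (n %% 2L != 0L) stop("`n` must be even", call. = FALSE)
  withr::local_seed(seed)
  as_dataset(matrix(rnorm(n * p), nrow = n, ncol = p),
             rep(1:2, each = n %/% 2L))
}

#' Simulate data where the classes differ only in variance
#'
#' A "complex separation" design: every variable has mean 50 in both
#' classes. The `p_null` null variables have variance 12.5 in both classes;
#' the 20 informative variables (the first 20 columns) keep variance 12.5
#' in class 1 but shrink to 12.5 / `variance_ratio` in class 2, nesting the
#' class-2 cloud inside class 1. Defaults: 50 training samples per class,
#' `variance_ratio = 4` (class-2 variance 3.125).
#'
#' @param p_null Number of null variables (980 and 9980 are the standard
#'   design points).
#' @param seed Integer RNG seed.
#' @param n_per_class Training samples per class.
#' @param n_test_per_class Test samples per class.
#' @param variance_ratio Class-1 over class-2 variance on the informative
#'   variables; `1` removes the separation entirely (test hook).
#' @return A list with tibbles `train` and `test`.
#' @examples
#' d <- simulate_variance_shift(p_null = 30, seed = 1, n_per_class = 10,
#'                              n_test_per_class = 10)
#' @export
simulate_variance_shift <- function(p_null = 980, seed = 1L,
                                    n_per_class = 50, n_test_per_class = 500,
                                    variance_ratio = 4) {
  p <- p_null + 20L
  sd_null <- sqrt(12.5)
  sd_inf2 <- sqrt(12.5 / variance_ratio)
  draw <- function(n) {
    X1 <- matrix(50 + sd_null * rnorm(n * p), nrow = n)
    X2 <- matrix(50 + sd_null * rnorm(n * p), nrow = n)
    X2[, 1:20] <- 50 + sd_inf2 * (X2[, 1:20] - 50) / sd_null
    as_dataset(rbind(X1, X2), rep(1:2, each = n))
  }
  withr::local_seed(seed)
  list(train = draw(n_per_class), test = draw(n_test_per_class))
}

#' Build a class-imbalanced null fixture
#'
#' Null-feature dataset with `n_min` class-1 and `n_max` class-2 samples,
#' used to exercise the majority-class down-sizing operator.
#'
#' @param n_min,n_max Class-1 and class-2 sample counts, `n_min < n_max`
#'   unless already balanced.
#' @param p Number of (null) variables.
#' @param seed Integer RNG seed.
#' @return A labeled tibble.
#' @examples
#' table(make_imbalanced_fixture(34, 211, p = 10, seed = 1)$class)
#' @export
make_imbalanced_fixture <- function(n_min, n_max, p, seed = 1L) {
  if (n_min > n_max) stop("`n_min` must not exceed `n_max`", call. = FALSE)
  withr::local_seed(seed)
  n <- n_min + n_max
  as_dataset(matrix(rnorm(n * p), nrow = n, ncol = p),
             rep(1:2, times = c(n_min, n_max)))
}

#' Read and write labeled datasets as delimited text
#'
#' Datasets round-trip losslessly at full double precision as
#' tab-separated text with a header row and an integer `class` column.
#'
#' @param data A labeled tibble.
#' @param path File path.
#' @return `write_dataset()` returns `data` invisibly; `read_dataset()`
#'   returns a labeled tibble.
#' @examples
#' d <- simulate_null_independent(p = 3, n = 4, seed = 1)
#' f <- tempfile(fileext = ".tsv")
#' write_dataset(d, f)
#' all.equal(read_dataset(f), d)
#' @export
write_dataset <- function(data, path) {
  dataset_matrix(data) # validates
  readr::write_tsv(data, path)
  invisible(data)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  out$class <- as.integer(out$class)
  out
}

#' Serialize a simulation configuration as YAML
#'
#' @param config A [sim_config()].
#' @param path File path.
#' @return `write_sim_config()` returns `config` invisibly;
#'   `read_sim_config()` returns a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(config)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}
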