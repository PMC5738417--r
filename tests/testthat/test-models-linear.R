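# synthetic feature problems with known structure
sep_problem <- function(n_per = 200L, d = 104L, shift = 3, seed = 1L) {
  withr::local_seed(seed)
  X <- rbind(matrix(rnorm(n_per * d), n_per),
             matrix(rnorm(n_per * d, shift / sqrt(d) * 10), n_per))
  colnames(X) <- feature_names("nucleus")[seq_len(d)]
  list(X = X, y = rep(c("a", "b"), each = n_per))
}

test_that("linearly separable classes are classified almost perfectly", {
  pb <- sep_problem()
  sp <- fair_split(pb$y, seed = 4)
  for (kind in c("logistic_regression", "linear_svm", "random_forest")) {
    fit <- train_classifier(pb$X, pb$y, linear_config(kind, seed = 2), sp)
    expect_gte(fit$val_accuracy, 0.99)
  }
})

test_that("shuffled labels give chance-level validation accuracy", {
  pb <- sep_problem()
  withr::local_seed(8)
  y_shuf <- sample(pb$y)
  sp <- fair_split(y_shuf, seed = 4)
  fit <- train_classifier(pb$X, y_shuf,
                          linear_config("logistic_regression", seed = 2), sp)
  expect_lt(abs(fit$val_accuracy - 0.5), 0.1)
})

test_that("the random forest honours its configured size", {
  pb <- sep_problem(50L)
  cfg <- linear_config("random_forest", rf_estimators = 100L,
                       rf_max_depth = 8L, seed = 3)
  fit <- train_classifier(pb$X, pb$y, cfg, fair_split(pb$y, seed = 1))
  expect_equal(fit$fit$num.trees, 100)
  expect_identical(fit$config$rf_max_depth, 8L)
  expect_lte(max(ranger::treeInfo(fit$fit, 1)$depth %||% 0, na.rm = TRUE), 8)
})

test_that("training rejects degenerate inputs and overlapping splits", {
  pb <- sep_problem(20L)
  expect_error(train_classifier(pb$X[1:20, ], rep("a", 20)), "two classes")
  bad_split <- list(train = 1:30, validation = 25:40)
  expect_error(train_classifier(pb$X, pb$y,
                                linear_config("logistic_regression"),
                                bad_split), "overlap")
})

test_that("ablating an uninformative group barely moves accuracy", {
  withr::local_seed(11)
  n <- 300
  signal <- matrix(rnorm(2 * n, rep(c(0, 2), each = n)), ncol = 1)
  noise <- matrix(rnorm(2 * n * 9), ncol = 9)
  X <- cbind(signal, noise)
  colnames(X) <- c("signal", paste0("noise_", 1:9))
  y <- rep(c("a", "b"), each = n)
  sp <- fair_split(y, seed = 5)
  groups <- list(noise = paste0("noise_", 1:9), signal = "signal")
  tab <- feature_ablation(X, y, groups,
                          linear_config("logistic_regression", seed = 6), sp)
  expect_identical(tab$features_used,
                   c("all features", "- noise", "- signal"))
  base <- tab$validation_accuracy[1]
  expect_lt(abs(tab$validation_accuracy[2] - base), 0.05)
  # removing the only informative feature collapses to chance
  expect_lt(tab$validation_accuracy[3], 0.65)
  # same seed, same data: identical table
  tab2 <- feature_ablation(X, y, groups,
                           linear_config("logistic_regression", seed = 6), sp)
  expect_identical(tab, tab2)
})

test_that("ablation handles empty group lists and unknown columns", {
  pb <- sep_problem(30L, d = 10L)
  sp <- fair_split(pb$y, seed = 3)
  tab <- feature_ablation(pb$X, pb$y, groups = list(),
                          linear_config("logistic_regression"), sp)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$features_used, "all features")
  expect_error(feature_ablation(pb$X, pb$y, list(bad = "nope"),
                                linear_config("logistic_regression"), sp),
               "unknown columns")
})

test_that("default feature groups mirror the ablation-table structure", {
  g <- default_feature_groups()
  expect_named(g, c("texture", "shape", "pftas", "lbp", "zernike", "area",
                    "eccentricity", "major_axis_length", "minor_axis_length",
                    "roundness"))
  expect_length(g$texture, 99)
  expect_length(g$shape, 5)
  expect_length(g$pftas, 54)
  expect_length(g$lbp, 20)
  expect_length(g$zernike, 25)
})

test_that("tidy and glance expose coefficients and accuracies", {
  pb <- sep_problem(50L, d = 12L)
  fit <- train_classifier(pb$X, pb$y,
                          linear_config("logistic_regression", seed = 2),
                          fair_split(pb$y, seed = 1))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate") %in% names(td)))
  gl <- glance(fit)
  expect_identical(gl$kind, "logistic_regression")
  expect_true(gl$val_accuracy >= 0 && gl$val_accuracy <= 1)
})
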