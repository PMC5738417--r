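test_that("the VGG adaptation has the mandated layer structure", {
  net <- build_vgg(128L, 2L)
  types <- vapply(net$layers, `[[`, "", "type")
  expect_identical(sum(types == "conv"), 10L)
  expect_identical(sum(types == "pool"), 4L)
  expect_identical(sum(types == "prelu"), 10L)  # PReLU after every conv
  expect_identical(sum(types == "dense"), 3L)   # 2 hidden + output
  expect_identical(sum(types == "relu"), 2L)    # ReLU after the FC layers
  expect_identical(types[1], "bn_input")

  # filters start at 32 and double after each pool: 32,32,64,64,...,512,512
  filt <- vapply(net$layers[types == "conv"], function(l) nrow(l$W), 1L)
  expect_identical(filt, c(32L, 32L, 64L, 64L, 128L, 128L,
                           256L, 256L, 512L, 512L))
  # kernel size 3 everywhere: W has 9 * C columns
  cin <- c(1L, head(filt, -1))
  expect_identical(vapply(net$layers[types == "conv"],
                          function(l) ncol(l$W), 1L), 9L * cin)
  # after 4 pools a 128-px input is 8x8, so the first FC sees 512*8*8
  first_dense <- net$layers[[which(types == "dense")[1]]]
  expect_identical(ncol(first_dense$W), 512L * 8L * 8L)

  expect_error(build_vgg(100L, 2L), "divisible by 16")
})

test_that("class weights are inverse-frequency with mean one", {
  expect_equal(unname(class_weights(rep(c("a", "b"), each = 10))), c(1, 1))
  expect_equal(unname(class_weights(rep(c("a", "b"), c(300, 100)))),
               c(0.5, 1.5))
  expect_error(class_weights(factor(c("a", "a"), levels = c("a", "b"))))
})

tiny_data <- function(n_per = 10L, hw = 16L, seed = 1L, sep = TRUE) {
  withr::local_seed(seed)
  dark <- replicate(n_per, matrix(as.integer(pmax(rnorm(hw^2, 500, 50), 0)), hw))
  mean2 <- if (sep) 2500 else 500
  bright <- replicate(n_per, matrix(as.integer(pmin(rnorm(hw^2, mean2, 50), 4095)), hw))
  x <- array(c(dark, bright), c(hw, hw, 2L * n_per))
  list(x = x, y = rep(c("dark", "bright"), each = n_per))
}

test_that("softmax probabilities are normalised and predictions shaped", {
  td <- tiny_data()
  net <- build_vgg(16L, 2L, seed = 1)
  p <- suppressWarnings(predict(net, td$x))
  expect_identical(dim(p), c(20L, 2L))
  expect_equal(unname(rowSums(p)), rep(1, 20), tolerance = 1e-6)
})

test_that("training is deterministic under a fixed seed", {
  td <- tiny_data()
  sp <- list(train = c(1:8, 11:18), validation = c(9, 10, 19, 20))
  cfg <- net_config(learning_rate = 1e-3, batch_size = 8L, patience = 5L,
                    eval_every = 2L, max_steps = 6L, seed = 7)
  n1 <- train_cnn(build_vgg(16L, 2L, seed = 3), td$x, td$y, sp, cfg)
  n2 <- train_cnn(build_vgg(16L, 2L, seed = 3), td$x, td$y, sp, cfg)
  expect_identical(n1$history, n2$history)
})

test_that("a separable toy problem is learned and evaluated correctly", {
  td <- tiny_data(n_per = 12L)
  sp <- fair_split(td$y, fraction = 0.3, seed = 2)
  cfg <- net_config(learning_rate = 2e-3, batch_size = 8L, patience = 20L,
                    eval_every = 5L, max_steps = 40L, seed = 1)
  net <- train_cnn(build_vgg(16L, 2L, seed = 1), td$x, td$y, sp, cfg)
  ev <- evaluate_model(net, td$x, td$y, sp$validation)
  expect_equal(ev$accuracy, 1)
  cm <- unclass(ev$confusion)
  expect_equal(unname(rowSums(cm)),
               as.numeric(table(td$y[sp$validation])))
  # best model is the best-validation state, not the last
  gl <- glance(net)
  expect_identical(gl$val_loss, min(tidy(net)$val_loss))
})

test_that("early stopping triggers on unlearnable labels", {
  td <- tiny_data(n_per = 10L, sep = FALSE)
  withr::local_seed(4)
  y <- sample(td$y)
  sp <- fair_split(y, fraction = 0.3, seed = 3)
  cfg <- net_config(learning_rate = 1e-3, batch_size = 8L, patience = 3L,
                    eval_every = 2L, max_steps = 200L, seed = 2)
  net <- train_cnn(build_vgg(16L, 2L, seed = 2), td$x, td$y, sp, cfg)
  expect_lt(max(tidy(net)$step), 200L)
})

test_that("divergence aborts with a diagnostic", {
  td <- tiny_data()
  td$x[, , 1:20] <- NA_integer_  # poisoned inputs make the loss non-finite
  sp <- list(train = c(1:8, 11:18), validation = c(9, 10, 19, 20))
  cfg <- net_config(learning_rate = 1e-3, batch_size = 8L,
                    eval_every = 5L, max_steps = 30L, seed = 1)
  expect_error(train_cnn(build_vgg(16L, 2L, seed = 1), td$x, td$y, sp, cfg),
               class = "nm_divergence")
})
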