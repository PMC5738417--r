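# VGG-style nucleus classifier.
#
# Architecture: input batch normalisation (with scaling), then 10
# convolutional layers (kernel 3, PReLU) in five blocks of two, max pooling
# (kernel 2, stride 2) after each of the first four blocks, filters
# starting at 32 and doubling after every pool (32-64-128-256-512), two
# fully connected ReLU layers (512, 512) with dropout 0.5, and a softmax
# output. Training uses weighted cross-entropy, Adam, and patience-based
# early stopping; the reported model is the parameter state at the best
# validation loss.

#' Training configuration for the CNN
#'
#' Defaults follow the reference training protocol: learning rate 8e-5,
#' batch size 32 for full nuclei (use 128 for patches), early-stopping
#' patience of 20 evaluation steps (one evaluation every `eval_every`
#' mini-batch updates).
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param patience Early-stopping patience, in evaluation steps (>= 1).
#' @param eval_every Mini-batch updates between validation evaluations.
#' @param max_steps Hard cap on mini-batch updates (scales runs down).
#' @param class_weights Optional positive per-class weight vector (mean 1);
#'   computed from the training labels with [class_weights()] when `NULL`.
#' @param seed Integer seed controlling initialisation, batch order and
#'   dropout.
#' @return An `nm_net_config`.
#' @export
net_config <- function(learning_rate = 8e-5, batch_size = 32L,
                       patience = 20L, eval_every = 20L, max_steps = 2000L,
                       class_weights = NULL, seed = 1L) {
  if (patience < 1) abort("`patience` must be >= 1")
  if (!is.null(class_weights) && any(class_weights <= 0)) {
    abort("class weights must be strictly positive")
  }
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 eval_every = as.integer(eval_every),
                 max_steps = as.integer(max_steps),
                 class_weights = class_weights, seed = as.integer(seed)),
            class = "nm_net_config")
}

#' Inverse-frequency class weights
#'
#' Weights proportional to `1 / n_k`, normalised to mean 1, so that rare
#' classes contribute as much loss as common ones.
#'
#' @param labels Training labels (>= 1 example per class).
#' @return Named positive weight vector with mean 1.
#' @examples
#' class_weights(rep(c("a", "b"), c(300, 100)))  # 0.5, 1.5
#' @export
class_weights <- function(labels) {
  n <- table(as.character(labels))
  if (length(n) < 2) abort("class weighting needs at least two classes")
  if (any(n == 0)) abort("every class needs at least one example")
  w <- 1 / as.numeric(n)
  w <- w / mean(w)
  setNames(w, names(n))
}

#' Build the VGG-adaptation network
#'
#' @param input_hw Input side in pixels; must be divisible by 16 (four
#'   2x2 pools).
#' @param n_classes Number of output classes.
#' @param seed Seed for He-initialised weights.
#' @return An untrained `nm_net`.
#' @export
build_vgg <- function(input_hw, n_classes, seed = 1L) {
  if (input_hw %% 16 != 0) abort("`input_hw` must be divisible by 16")
  withr::local_seed(seed)
  layers <- list(nn_layer("bn_input", gamma = 1, beta = 0,
                          run_mean = 0, run_var = 1))
  filters <- c(32L, 64L, 128L, 256L, 512L)
  C <- 1L
  for (b in seq_along(filters)) {
    f <- filters[b]
    for (k in 1:2) {
      layers <- c(layers, list(
        nn_layer("conv", W = nn_he_init(f, 9L * C, 9L * C), b = rep(0, f)),
        nn_layer("prelu", alpha = 0.25)))
      C <- f
    }
    if (b < 5) layers <- c(layers, list(nn_layer("pool")))
  }
  side <- input_hw %/% 16L
  flat <- 512L * side * side
  layers <- c(layers, list(
    nn_layer("flatten"),
    nn_layer("dense", W = nn_he_init(512L, flat, flat), b = rep(0, 512)),
    nn_layer("relu"),
    nn_layer("dropout", rate = 0.5),
    nn_layer("dense", W = nn_he_init(512L, 512L, 512L), b = rep(0, 512)),
    nn_layer("relu"),
    nn_layer("dropout", rate = 0.5),
    nn_layer("dense", W = nn_he_init(n_classes, 512L, 512L),
             b = rep(0, n_classes))))
  structure(list(layers = layers, n_classes = as.integer(n_classes),
                 input_hw = as.integer(input_hw), classes = NULL,
                 trained = FALSE,
                 penultimate_at = length(layers) - 1L,
                 arch = "vgg"),
            class = "nm_net")
}

#' @export
print.nm_net <- function(x, ...) {
  tl <- table(vapply(x$layers, `[[`, "", "type"))
  cat(sprintf("<nm_net> %s, input %dx%d, %d classes%s\n", x$arch,
              x$input_hw, x$input_hw, x$n_classes,
              if (x$trained) " (trained)" else " (untrained)"))
  cat("  layers:", paste(names(tl), tl, sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' Summarise a network's layer structure
#'
#' @param net An `nm_net`.
#' @return Tibble with one row per layer (`type`, `n_params`).
#' @export
net_spec_table <- function(net) {
  bind_rows(lapply(net$layers, function(l) {
    pn <- intersect(names(l), c("W", "b", "alpha", "gamma", "beta"))
    tibble(type = l$type,
           n_params = sum(vapply(l[pn], length, 1L)))
  }))
}

as_input_array <- function(x) {
  # accepts (H, W, N) array or list of matrices; scales counts to [0, 1]
  if (is.list(x)) x <- simplify2array(x)
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1L)
  x / MAX_COUNT
}

#' Train a CNN
#'
#' Mini-batch Adam on a class-weighted cross-entropy. Batches are sampled
#' evenly across classes from the training split; validation loss is
#' evaluated every `eval_every` updates and training stops once it has
#' failed to improve for `patience` evaluations (or at `max_steps`). The
#' returned model carries the parameters of the best validation evaluation,
#' not the last one.
#'
#' @param net An `nm_net` from [build_vgg()] or [build_patchnet()].
#' @param x Input images: `(H, W, N)` array of 12-bit counts, or a list of
#'   matrices.
#' @param y Labels, length N.
#' @param split An [fair_split()] result (or list with `train`/`validation`
#'   indices).
#' @param config A [net_config()].
#' @return A trained `nm_net` with a `history` tibble (step, training and
#'   validation loss/accuracy at each evaluation).
#' @export
train_cnn <- function(net, x, y, split, config = net_config()) {
  xs <- as_input_array(x)
  y <- as.character(y)
  stopifnot(dim(xs)[3] == length(y))
  classes <- sort(unique(y))
  if (length(classes) < 2) abort("training needs at least two classes")
  y_idx <- match(y, classes)
  cw <- config$class_weights %||% class_weights(y[split$train])
  if (is.null(names(cw))) names(cw) <- classes
  cw <- cw[classes]

  withr::local_seed(config$seed)
  net <- nn_adam_init(net)
  net$classes <- classes

  tr_by_class <- split(split$train, y[split$train])
  per_class <- max(1L, config$batch_size %/% length(classes))
  val_idx <- split$validation

  best_loss <- Inf; best_net <- NULL; bad <- 0L
  hist_rows <- list()
  acc_loss <- c(); acc_acc <- c()

  for (step in seq_len(config$max_steps)) {
    bi <- unlist(lapply(tr_by_class, function(ii)
      ii[sample.int(length(ii), per_class, replace = per_class > length(ii))]))
    xb <- array(xs[, , bi], c(1L, dim(xs)[1], dim(xs)[2], length(bi)))
    fwd <- nn_forward(net, xb, training = TRUE)
    net <- fwd$net
    loss <- nn_loss(fwd$probs, y_idx[bi], cw)
    if (!is.finite(loss)) {
      abort(sprintf("training diverged (non-finite loss at step %d)", step),
            class = "nm_divergence")
    }
    grads <- nn_backward(net, fwd, y_idx[bi], cw)
    net <- nn_adam_step(net, grads, config$learning_rate)
    acc_loss <- c(acc_loss, loss)
    acc_acc <- c(acc_acc, mean(max.col(t(fwd$probs)) == y_idx[bi]))

    if (step %% config$eval_every == 0 || step == config$max_steps) {
      ev <- nn_evaluate(net, xs, y_idx, val_idx, cw)
      hist_rows[[length(hist_rows) + 1L]] <-
        tibble(step = step, train_loss = mean(acc_loss),
               train_accuracy = mean(acc_acc),
               val_loss = ev$loss, val_accuracy = ev$accuracy)
      acc_loss <- c(); acc_acc <- c()
      if (ev$loss < best_loss - 1e-9) {
        best_loss <- ev$loss
        best_net <- nn_snapshot(net)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= config$patience) break
      }
    }
  }
  out <- best_net %||% nn_snapshot(net)
  out$trained <- TRUE
  out$history <- bind_rows(hist_rows)
  out$config <- config
  out
}

nn_evaluate <- function(net, xs, y_idx, idx, cw, chunk = 128L) {
  losses <- c(); ns <- c(); correct <- 0L
  for (start in seq(1L, length(idx), by = chunk)) {
    ii <- idx[start:min(start + chunk - 1L, length(idx))]
    xb <- array(xs[, , ii], c(1L, dim(xs)[1], dim(xs)[2], length(ii)))
    fwd <- nn_forward(net, xb, training = FALSE)
    losses <- c(losses, nn_loss(fwd$probs, y_idx[ii], cw))
    ns <- c(ns, length(ii))
    correct <- correct + sum(max.col(t(fwd$probs)) == y_idx[ii])
  }
  list(loss = sum(losses * ns) / sum(ns), accuracy = correct / length(idx))
}

#' Predict class probabilities
#'
#' @param object A trained `nm_net`.
#' @param x Input images as for [train_cnn()].
#' @param type `"prob"` (default), `"class"`, or `"penultimate"` (the
#'   activations feeding the output layer, e.g. for embedding).
#' @param ... Unused.
#' @return Probability matrix (rows sum to 1), class vector, or activation
#'   matrix, one row per input.
#' @export
predict.nm_net <- function(object, x, type = c("prob", "class", "penultimate"),
                           ...) {
  type <- match.arg(type)
  if (!object$trained && type != "penultimate") {
    warn("predicting from an untrained network")
  }
  xs <- as_input_array(x)
  n <- dim(xs)[3]
  out <- NULL
  for (start in seq(1L, n, by = 256L)) {
    ii <- start:min(start + 255L, n)
    xb <- array(xs[, , ii], c(1L, dim(xs)[1], dim(xs)[2], length(ii)))
    fwd <- nn_forward(object, xb, training = FALSE)
    block <- if (type == "penultimate") t(fwd$penultimate) else t(fwd$probs)
    out <- rbind(out, block)
  }
  if (type == "class") {
    return(object$classes[max.col(out)])
  }
  if (type == "prob" && !is.null(object$classes)) colnames(out) <- object$classes
  out
}

#' Evaluate a trained model on a split
#'
#' @param net Trained `nm_net`.
#' @param x,y Inputs and labels.
#' @param idx Indices to evaluate (e.g. `split$validation`).
#' @return List with `confusion` (an `nm_confusion`) and `accuracy`.
#' @export
evaluate_model <- function(net, x, y, idx = NULL) {
  y <- as.character(y)
  idx <- idx %||% seq_along(y)
  xs <- as_input_array(x)
  pred <- predict(net, xs[, , idx, drop = FALSE] * MAX_COUNT, type = "class")
  cm <- confusion_matrix(y[idx], pred)
  list(confusion = cm, accuracy = accuracy(cm))
}

#' @export
tidy.nm_net <- function(x, ...) {
  if (is.null(x$history)) abort("no training history: train the model first")
  x$history
}

#' @export
glance.nm_net <- function(x, ...) {
  h <- x$history
  best <- h[which.min(h$val_loss), ]
  tibble(steps = max(h$step), best_step = best$step,
         val_loss = best$val_loss, val_accuracy = best$val_accuracy,
         n_params = sum(net_spec_table(x)$n_params))
}
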