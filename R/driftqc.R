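# Drift-blur quality control.
#
# Specimen drift during acquisition destroys nuclear texture while leaving
# the pixel-value histogram essentially unchanged, so it cannot be caught
# by per-image statistics. Instead, acquisition sets of the same class are
# tested for machine distinguishability: if a classifier can tell one set
# apart from every other same-class set with validation accuracy
# consistently above a threshold (default 60%), that set is discarded.

#' Default drift-QC trainer: ridge logistic regression on morphometric features
#'
#' Satisfies the trainer contract `function(X_train, y_train, X_val, y_val,
#' seed) -> validation accuracy`. Texture features are directly sensitive
#' to the high-frequency content that drift blur removes, and sit at
#' chance for i.i.d. sets. The ridge penalty is deliberately strong
#' (default lambda 1): set comparisons run at small sample sizes where the
#' feature dimension rivals the number of nuclei, and a weakly regularised
#' model separates even identically distributed sets by chance.
#'
#' @param regularization Ridge penalty (default 1).
#' @return A trainer function.
#' @export
feature_trainer <- function(regularization = 1) {
  function(X_train, y_train, X_val, y_val, seed = 1L) {
    n <- length(y_train)
    fit <- train_classifier(rbind(X_train, X_val),
                            c(y_train, y_val),
                            linear_config("logistic_regression",
                                          regularization = regularization,
                                          seed = seed),
                            split = list(train = seq_len(n),
                                         validation = n + seq_along(y_val)))
    fit$val_accuracy
  }
}

#' CNN drift-QC trainer (patch-scale network, reduced patience)
#'
#' Alternative trainer using the patch-scale CNN on downsampled crops;
#' slower than [feature_trainer()] but closer to the reference protocol.
#'
#' @param input_hw Downsampled input side (must divide by 16).
#' @param max_steps Training-step cap.
#' @return A trainer function over feature matrices of flattened images.
#' @export
cnn_trainer <- function(input_hw = 32L, max_steps = 60L) {
  function(X_train, y_train, X_val, y_val, seed = 1L) {
    to_array <- function(M) {
      a <- array(t(M), c(input_hw, input_hw, nrow(M)))
      a
    }
    x <- abind_3(to_array(X_train), to_array(X_val))
    y <- c(y_train, y_val)
    split <- list(train = seq_along(y_train),
                  validation = length(y_train) + seq_along(y_val))
    net <- build_vgg(input_hw, length(unique(y)), seed = seed)
    cfg <- net_config(learning_rate = 1e-3, batch_size = 16L, patience = 5L,
                      eval_every = 10L, max_steps = max_steps, seed = seed)
    net <- train_cnn(net, x, y, split, cfg)
    ev <- evaluate_model(net, x, y, split$validation)
    ev$accuracy
  }
}

abind_3 <- function(a, b) {
  out <- array(0, c(dim(a)[1:2], dim(a)[3] + dim(b)[3]))
  out[, , seq_len(dim(a)[3])] <- a
  out[, , dim(a)[3] + seq_len(dim(b)[3])] <- b
  out
}

# downsample a square matrix by integer block averaging
downsample_crop <- function(m, out_side) {
  f <- nrow(m) %/% out_side
  stopifnot(f * out_side == nrow(m))
  grp_r <- rep(seq_len(out_side), each = f)
  grp_c <- rep(seq_len(out_side), each = f)
  rowsum(t(rowsum(m, grp_r)), grp_c) / f^2
}

#' Flag drift-blurred acquisition sets
#'
#' For every unordered pair of same-class sets, a binary classifier is
#' trained to distinguish the two (fair split, one model per repeat with
#' distinct split seeds). A set is flagged as drift-blurred iff its
#' validation accuracy against every other set exceeds `threshold` in
#' every repeat ("consistently distinguishable").
#'
#' @param sets Named list of nucleus-record lists, one per acquisition set,
#'   all of the same biological class.
#' @param trainer Trainer function (see [feature_trainer()], the default).
#' @param threshold Accuracy threshold (default 0.60).
#' @param repeats Number of repeated splits (default 3).
#' @param fraction Validation fraction for each comparison split.
#' @param seed Master seed.
#' @param features Optional precomputed list of feature matrices parallel
#'   to `sets` (rows = nuclei); computed with [assemble_features()]
#'   otherwise.
#' @return List with `flagged` (character vector of set names) and
#'   `comparisons` (tibble: set_a, set_b, repeat, val_accuracy).
#' @export
flag_drift_sets <- function(sets, trainer = feature_trainer(),
                            threshold = 0.60, repeats = 3L, fraction = 0.15,
                            seed = 1L, features = NULL) {
  nm <- names(sets) %||% as.character(seq_along(sets))
  if (length(sets) < 2) {
    warn("fewer than two sets: nothing to compare")
    return(list(flagged = character(),
                comparisons = tibble(set_a = character(), set_b = character(),
                                     rep = integer(), val_accuracy = double())))
  }
  if (is.null(features)) {
    features <- lapply(sets, function(rs) feature_matrix(assemble_features(rs)))
  }
  rows <- list()
  for (i in seq_len(length(sets) - 1L)) for (j in (i + 1L):length(sets)) {
    X <- rbind(features[[i]], features[[j]])
    y <- rep(c("a", "b"), c(nrow(features[[i]]), nrow(features[[j]])))
    for (r in seq_len(repeats)) {
      sp <- fair_split(y, fraction = fraction,
                       seed = derive_seed(seed, i * 1000L + j * 10L + r))
      acc <- trainer(X[sp$train, , drop = FALSE], y[sp$train],
                     X[sp$validation, , drop = FALSE], y[sp$validation],
                     seed = derive_seed(seed, r))
      rows[[length(rows) + 1L]] <- tibble(set_a = nm[i], set_b = nm[j],
                                          rep = r, val_accuracy = acc)
    }
  }
  comparisons <- bind_rows(rows)
  flagged <- nm[vapply(nm, function(s) {
    rel <- comparisons$set_a == s | comparisons$set_b == s
    all(comparisons$val_accuracy[rel] > threshold)
  }, TRUE)]
  list(flagged = flagged, comparisons = comparisons)
}
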