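# Shared evaluation utilities: fair train/validation splits, confusion
# matrices, accuracy, and 2-D embeddings of learned representations.

#' Fair train/validation split
#'
#' Draws a validation set totalling at most `fraction` of the data with
#' equal per-class counts: each class contributes
#' `floor(fraction * n_total / n_classes)` examples (floor rounding), the
#' remainder goes to training. Deterministic under `seed`.
#'
#' @param labels Vector of class labels.
#' @param fraction Maximum validation share of the whole data set
#'   (default 0.15).
#' @param seed Integer seed.
#' @return An `nm_split`: list with `train` and `validation` index vectors.
#' @examples
#' sp <- fair_split(rep(c("a", "b"), each = 500), seed = 1)
#' lengths(sp)  # 850 train, 150 validation (75 per class)
#' @export
fair_split <- function(labels, fraction = 0.15, seed = 1L) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (any(table(labels) < 2)) abort("every class needs at least 2 examples")
  per_class <- floor(fraction * length(labels) / length(classes))
  withr::local_seed(seed)
  val <- integer()
  for (cl in classes) {
    idx <- which(labels == cl)
    if (per_class >= length(idx)) {
      abort(sprintf("class '%s' too small for a fair split (%d needed, %d present)",
                    cl, per_class + 1L, length(idx)))
    }
    if (per_class > 0) val <- c(val, sort(sample(idx, per_class)))
  }
  structure(list(train = setdiff(seq_along(labels), val),
                 validation = sort(val), seed = seed),
            class = "nm_split")
}

#' Confusion matrix
#'
#' Rows index the reference class, columns the prediction. Predicted labels
#' unseen in the reference add a column with a warning.
#'
#' @param reference,predictions Equal-length label vectors.
#' @return An `nm_confusion` (integer matrix with class dimnames).
#' @export
confusion_matrix <- function(reference, predictions) {
  if (length(reference) != length(predictions)) {
    abort("reference and predictions must have equal length")
  }
  reference <- as.character(reference)
  predictions <- as.character(predictions)
  ref_classes <- sort(unique(reference))
  extra <- setdiff(unique(predictions), ref_classes)
  if (length(extra)) {
    warn(sprintf("predicted label(s) not in the reference: %s",
                 paste(extra, collapse = ", ")))
  }
  classes <- c(ref_classes, sort(extra))
  cm <- table(factor(reference, levels = classes),
              factor(predictions, levels = classes))
  structure(unclass(cm)[ref_classes, classes, drop = FALSE],
            class = "nm_confusion")
}

#' @export
print.nm_confusion <- function(x, ...) {
  cat("Reference \\ Predictions\n")
  print(unclass(x))
  cat(sprintf("accuracy: %.3f\n", accuracy(x)))
  invisible(x)
}

#' Classification accuracy from a confusion matrix
#'
#' `trace / total` over the reference classes.
#'
#' @param cm An `nm_confusion` matrix.
#' @return Fraction correct.
#' @export
accuracy <- function(cm) {
  stopifnot(inherits(cm, "nm_confusion"))
  m <- unclass(cm)
  shared <- intersect(rownames(m), colnames(m))
  sum(diag(m[shared, shared, drop = FALSE])) / sum(m)
}

#' Embed representations in 2-D with t-SNE
#'
#' Seeded wrapper around Barnes-Hut t-SNE for visualising learned
#' representations (penultimate CNN activations or raw feature vectors).
#'
#' @param representations Numeric matrix, one row per example.
#' @param seed Integer seed.
#' @param perplexity t-SNE perplexity; default adapts to small inputs.
#' @return Tibble with `dim1`, `dim2`, one row per input row.
#' @export
tsne_embed <- function(representations, seed = 1L, perplexity = NULL) {
  representations <- as.matrix(representations)
  n <- nrow(representations)
  if (n < 2) abort("need at least 2 rows to embed")
  perplexity <- perplexity %||% max(min(30, floor((n - 1) / 3)), 1)
  if (n - 1 < 3 * perplexity) abort("too few rows for the requested perplexity")
  withr::local_seed(seed)
  fit <- Rtsne::Rtsne(representations, dims = 2, perplexity = perplexity,
                      check_duplicates = FALSE, pca = ncol(representations) > 50,
                      verbose = FALSE, num_threads = 1)
  tibble(dim1 = fit$Y[, 1], dim2 = fit$Y[, 2])
}
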