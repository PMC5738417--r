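# Patch-level interpretable classifier.
#
# One small CNN is applied with shared weights to every patch of a nucleus
# crop; the per-patch class probabilities are averaged to classify the
# whole nucleus. Because the classifier sees only a small receptive field,
# its per-patch decisions form a spatial map of which nuclear regions drive
# the classification (global heat-map), and the last convolutional layer's
# activations give per-filter maps.

#' Build the patch-scale classifier
#'
#' Three 3x3 convolutional layers with PReLU activations (receptive field
#' 7 px, within the smallest supported patch), global average pooling and a
#' softmax output. Patch sizes are odd so a patch centres on a pixel;
#' the reference choices are 11 (easy tasks) and 17 (harder tasks, more
#' context).
#'
#' @param patch_size Odd patch side, px.
#' @param n_classes Number of classes.
#' @param n_filters Filters per conv layer (default 16).
#' @param seed Seed for initialisation.
#' @return An untrained `nm_net` with `arch = "patchnet"`.
#' @export
build_patchnet <- function(patch_size, n_classes, n_filters = 16L, seed = 1L) {
  if (patch_size %% 2 == 0) abort("`patch_size` must be odd")
  withr::local_seed(seed)
  f <- as.integer(n_filters)
  layers <- list(
    nn_layer("bn_input", gamma = 1, beta = 0, run_mean = 0, run_var = 1),
    nn_layer("conv", W = nn_he_init(f, 9L, 9L), b = rep(0, f)),
    nn_layer("prelu", alpha = 0.25),
    nn_layer("conv", W = nn_he_init(f, 9L * f, 9L * f), b = rep(0, f)),
    nn_layer("prelu", alpha = 0.25),
    nn_layer("conv", W = nn_he_init(f, 9L * f, 9L * f), b = rep(0, f)),
    nn_layer("prelu", alpha = 0.25),
    nn_layer("gap"),
    nn_layer("dense", W = nn_he_init(n_classes, f, f), b = rep(0, n_classes)))
  structure(list(layers = layers, n_classes = as.integer(n_classes),
                 input_hw = as.integer(patch_size), classes = NULL,
                 trained = FALSE, penultimate_at = length(layers) - 1L,
                 n_filters = f, arch = "patchnet"),
            class = "nm_net")
}

#' Classify a nucleus by averaging patch decisions
#'
#' Extracts the coverage-filtered patch lattice from the record, applies
#' the patch classifier to every patch, and averages the per-patch class
#' probabilities (plain arithmetic mean over retained patches) into the
#' image-level prediction. The per-patch decisions are returned as a global
#' heat-map tied to the lattice geometry.
#'
#' @param net Trained patch-scale `nm_net`.
#' @param record Nucleus record.
#' @param stride Heat-map lattice stride, px (default 4 for a dense map).
#' @param min_coverage Patch coverage filter.
#' @return List with `probs` (named image-level probability vector) and
#'   `heatmap` (`nm_heatmap` tibble: offsets, per-class probabilities,
#'   predicted class; geometry in attributes).
#' @export
predict_image <- function(net, record, stride = 4L, min_coverage = 0.85) {
  if (!net$trained) warn("predicting from an untrained network")
  patches <- extract_patches(record, size = net$input_hw, stride = stride,
                             min_coverage = min_coverage)
  if (length(patches) == 0) {
    abort("no patches pass the coverage filter", class = "nm_degenerate_input")
  }
  px <- simplify2array(lapply(patches, `[[`, "pixels"))
  probs <- predict(net, px, type = "prob")
  img_prob <- colMeans(probs)
  cls <- colnames(probs) %||% as.character(seq_len(ncol(probs)))
  hm <- tibble(offset_r = vapply(patches, function(p) p$offset[1], 1),
               offset_c = vapply(patches, function(p) p$offset[2], 1),
               as_tibble(probs),
               predicted = cls[max.col(probs)])
  attr(hm, "patch_size") <- net$input_hw
  attr(hm, "stride") <- as.integer(stride)
  attr(hm, "canvas") <- nrow(record$crop)
  class(hm) <- c("nm_heatmap", class(hm))
  list(probs = img_prob, heatmap = hm)
}

#' Per-filter activation maps from the last convolutional layer
#'
#' The patch classifier is fully convolutional up to its pooling stage, so
#' its convolution stack can be applied to the whole nucleus crop at once;
#' the result is one spatial activation map per last-layer filter, aligned
#' with the crop geometry.
#'
#' @param net Trained patch-scale `nm_net`.
#' @param record Nucleus record.
#' @return Array `(canvas, canvas, n_filters)` of activations.
#' @export
filter_heatmaps <- function(net, record) {
  if (!net$trained) abort("filter heat-maps need a trained model")
  if (net$arch != "patchnet") abort("filter heat-maps are defined for the patch classifier")
  x <- array(record$crop / MAX_COUNT, c(1L, dim(record$crop), 1L))
  for (l in net$layers) {
    if (l$type == "bn_input") {
      x <- l$gamma * (x - l$run_mean) / sqrt(l$run_var + 1e-5) + l$beta
    } else if (l$type == "conv") {
      x <- conv_fwd(l, x)$out
    } else if (l$type == "prelu") {
      neg <- x < 0
      x <- x * !neg + l$alpha * x * neg
    } else {
      break  # pooling and beyond are not spatial
    }
  }
  maps <- aperm(array(x, dim(x)[1:3]), c(2, 3, 1))
  dimnames(maps) <- list(NULL, NULL,
                         sprintf("filter_%02d", seq_len(dim(maps)[3])))
  maps
}

#' @export
autoplot.nm_heatmap <- function(object, class = NULL, ...) {
  cls <- class %||% setdiff(names(object),
                            c("offset_r", "offset_c", "predicted"))[1]
  sz <- attr(object, "patch_size")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$offset_c + sz / 2,
                               y = .data$offset_r + sz / 2,
                               fill = .data[[cls]])) +
    ggplot2::geom_tile(width = attr(object, "stride"),
                       height = attr(object, "stride")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column (px)", y = "row (px)",
                  fill = paste0("P(", cls, ")"),
                  title = "Per-patch classification decisions") +
    ggplot2::theme_minimal()
}
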