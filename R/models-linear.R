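# Linear baselines on morphometric features, with feature-ablation tables.
#
# Three classifiers: class-weighted L2-regularised logistic regression
# (glmnet ridge), a linear-kernel SVM (e1071), and a random forest with 100
# trees of maximum depth 8 (ranger). Features are z-scored on the training
# split for the logistic and SVM models; trees use raw features.

#' Linear-model configuration
#'
#' @param kind `"logistic_regression"`, `"linear_svm"`, or `"random_forest"`.
#' @param regularization Ridge penalty (lambda) for logistic regression, or
#'   cost for the SVM.
#' @param rf_estimators,rf_max_depth Random-forest size (default 100 trees,
#'   depth 8).
#' @param seed Integer seed.
#' @return An `nm_linear_config`.
#' @export
linear_config <- function(kind = c("logistic_regression", "linear_svm",
                                   "random_forest"),
                          regularization = 1e-2, rf_estimators = 100L,
                          rf_max_depth = 8L, seed = 1L) {
  kind <- match.arg(kind)
  if (regularization <= 0) abort("`regularization` must be > 0")
  structure(list(kind = kind, regularization = regularization,
                 rf_estimators = as.integer(rf_estimators),
                 rf_max_depth = as.integer(rf_max_depth),
                 seed = as.integer(seed)),
            class = "nm_linear_config")
}

#' Train a linear baseline classifier
#'
#' Fits the configured model on the training rows only and reports training
#' and validation accuracy. Class imbalance is handled by inverse-frequency
#' class weights ([class_weights()]).
#'
#' @param X Numeric feature matrix (rows = examples) or the tibble from
#'   [assemble_features()].
#' @param y Labels (>= 2 classes present).
#' @param config A [linear_config()].
#' @param split An [fair_split()] result.
#' @return An `nm_classifier` with `train_accuracy`, `val_accuracy`, and a
#'   [predict()] method.
#' @export
train_classifier <- function(X, y, config = linear_config(),
                             split = fair_split(y, seed = config$seed)) {
  if (is.data.frame(X)) X <- feature_matrix(X)
  X <- as.matrix(X)
  y <- as.character(y)
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2) abort("training needs at least two classes")
  if (length(intersect(split$train, split$validation))) {
    abort("train and validation indices overlap")
  }
  tr <- split$train; va <- split$validation
  cw <- class_weights(y[tr])
  withr::local_seed(config$seed)

  pad <- ncol(X) == 1L && config$kind == "logistic_regression"
  if (pad) X <- cbind(X, .pad = 0)  # glmnet needs >= 2 columns
  center <- colMeans(X[tr, , drop = FALSE])
  scale_ <- apply(X[tr, , drop = FALSE], 2, sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  Z <- sweep(sweep(X, 2, center), 2, scale_, "/")

  fit <- switch(
    config$kind,
    logistic_regression = {
      fam <- if (length(unique(y)) > 2) "multinomial" else "binomial"
      glmnet::glmnet(Z[tr, , drop = FALSE], factor(y[tr]), family = fam,
                     alpha = 0, lambda = config$regularization,
                     weights = cw[y[tr]], standardize = FALSE)
    },
    linear_svm = e1071::svm(Z[tr, , drop = FALSE], factor(y[tr]),
                            kernel = "linear", cost = 1,  # library default
                            class.weights = cw, scale = FALSE),
    random_forest = {
      df <- data.frame(.y = factor(y[tr]), X[tr, , drop = FALSE],
                       check.names = FALSE)
      ranger::ranger(dependent.variable.name = ".y", data = df,
                     num.trees = config$rf_estimators,
                     max.depth = config$rf_max_depth,
                     seed = config$seed, num.threads = 1)
    })

  obj <- structure(list(kind = config$kind, fit = fit, config = config,
                        center = center, scale = scale_, pad = pad,
                        classes = sort(unique(y[tr])), split = split),
                   class = "nm_classifier")
  acc_X <- if (pad) X[, 1, drop = FALSE] else X  # predict() re-pads
  obj$train_accuracy <- mean(predict(obj, acc_X[tr, , drop = FALSE]) == y[tr])
  obj$val_accuracy <- if (length(va)) {
    mean(predict(obj, acc_X[va, , drop = FALSE]) == y[va])
  } else NA_real_
  obj
}

#' @export
predict.nm_classifier <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- feature_matrix(newdata)
  newdata <- as.matrix(newdata)
  if (isTRUE(object$pad)) newdata <- cbind(newdata, .pad = 0)
  Z <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  switch(
    object$kind,
    logistic_regression = {
      p <- predict(object$fit, Z, type = "class")
      as.character(p)
    },
    linear_svm = as.character(predict(object$fit, Z)),
    random_forest = as.character(predict(object$fit,
                                         data.frame(newdata,
                                                    check.names = FALSE),
                                         num.threads = 1)$predictions))
}

#' @export
print.nm_classifier <- function(x, ...) {
  cat(sprintf("<nm_classifier> %s: train %.3f / validation %.3f\n",
              x$kind, x$train_accuracy, x$val_accuracy))
  invisible(x)
}

#' @export
glance.nm_classifier <- function(x, ...) {
  tibble(kind = x$kind, train_accuracy = x$train_accuracy,
         val_accuracy = x$val_accuracy,
         n_train = length(x$split$train),
         n_validation = length(x$split$validation))
}

#' @export
tidy.nm_classifier <- function(x, ...) {
  if (x$kind == "logistic_regression") {
    cf <- coef(x$fit)
    if (is.list(cf)) {
      bind_rows(lapply(names(cf), function(cl) {
        m <- as.matrix(cf[[cl]])
        tibble(class = cl, term = rownames(m), estimate = m[, 1])
      }))
    } else {
      m <- as.matrix(cf)
      tibble(term = rownames(m), estimate = m[, 1])
    }
  } else if (x$kind == "random_forest") {
    tibble(term = names(x$fit$variable.importance %||%
                          setNames(numeric(0), character(0))),
           importance = unname(x$fit$variable.importance %||% numeric(0)))
  } else {
    tibble(term = colnames(x$fit$SV),
           estimate = as.vector(t(x$fit$coefs) %*% x$fit$SV))
  }
}

#' Default feature-group definitions for ablation
#'
#' Mirrors the structure of the reference ablation analysis: the two
#' super-groups (all texture, all shape), the three texture blocks, and
#' each shape feature on its own.
#'
#' @param feature_names_ Column names of the feature matrix.
#' @return Named list of column-name vectors.
#' @export
default_feature_groups <- function(feature_names_ = feature_names("nucleus")) {
  grab <- function(p) feature_names_[grepl(p, feature_names_)]
  Filter(length, list(
    texture = grab("^(lbp|pftas|zernike)_"),
    shape = grab("^shape_"),
    pftas = grab("^pftas_"),
    lbp = grab("^lbp_"),
    zernike = grab("^zernike_"),
    area = grab("^shape_area$"),
    eccentricity = grab("^shape_eccentricity$"),
    major_axis_length = grab("^shape_major_axis_length$"),
    minor_axis_length = grab("^shape_minor_axis_length$"),
    roundness = grab("^shape_roundness$")))
}

#' Feature-ablation table
#'
#' Retrains the configured model once per feature group with that group's
#' columns removed, on the same split throughout; the first row is the
#' all-features baseline.
#'
#' @inheritParams train_classifier
#' @param groups Named list of feature-column sets to ablate (default
#'   [default_feature_groups()]).
#' @return An `nm_ablation` tibble: `features_used`, `n_features`,
#'   `train_accuracy`, `validation_accuracy`.
#' @export
feature_ablation <- function(X, y, groups = NULL,
                             config = linear_config(),
                             split = fair_split(y, seed = config$seed)) {
  if (is.data.frame(X)) X <- feature_matrix(X)
  X <- as.matrix(X)
  groups <- groups %||% default_feature_groups(colnames(X))
  unknown <- setdiff(unlist(groups), colnames(X))
  if (length(unknown)) {
    abort(sprintf("ablation group references unknown columns: %s",
                  paste(head(unknown, 3), collapse = ", ")))
  }
  fit0 <- train_classifier(X, y, config, split)
  rows <- list(tibble(features_used = "all features",
                      n_features = ncol(X),
                      train_accuracy = fit0$train_accuracy,
                      validation_accuracy = fit0$val_accuracy))
  for (g in names(groups)) {
    keep <- setdiff(colnames(X), groups[[g]])
    fit <- train_classifier(X[, keep, drop = FALSE], y, config, split)
    rows[[length(rows) + 1L]] <-
      tibble(features_used = paste0("- ", g), n_features = length(keep),
             train_accuracy = fit$train_accuracy,
             validation_accuracy = fit$val_accuracy)
  }
  out <- bind_rows(rows)
  class(out) <- c("nm_ablation", class(out))
  out
}

#' @export
autoplot.nm_ablation <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("train_accuracy", "validation_accuracy"),
                              names_to = "set", values_to = "accuracy")
  long$set <- sub("_accuracy", "", long$set)
  ggplot2::ggplot(long,
                  ggplot2::aes(x = factor(.data$features_used,
                                          levels = rev(unique(object$features_used))),
                               y = .data$accuracy, fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "accuracy", fill = NULL,
                  title = "Feature ablation") +
    ggplot2::theme_minimal()
}
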