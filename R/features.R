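# Shape features and feature-vector assembly.
#
# The full per-nucleus morphometric vector has 104 entries: 5 shape
# features (area, eccentricity, major and minor axis length, roundness)
# plus the 99 texture features of texture_features(). Patch vectors omit
# the shape block (patches carry no nucleus outline) and have 99 entries.

shape_feature_names <- c("shape_area", "shape_eccentricity",
                         "shape_major_axis_length", "shape_minor_axis_length",
                         "shape_roundness")

#' Shape features of a nucleus mask
#'
#' Area (pixel count), eccentricity and axis lengths from the mask's
#' second-moment ellipse (axis length = 4 sqrt(eigenvalue) of the pixel
#' covariance, the regionprops convention), and roundness `4*pi*A / P^2`
#' with the perimeter `P` estimated from the 4-neighbour boundary crack
#' count with the Cauchy-Crofton correction factor `pi/4` (exact for disks
#' on average over orientations); roundness is capped at 1.
#'
#' @param mask Logical matrix, a single connected component.
#' @return Named numeric vector of length 5.
#' @export
shape_features <- function(mask) {
  if (!any(mask)) abort("empty mask", class = "nm_degenerate_input")
  w <- which(mask, arr.ind = TRUE)
  area <- nrow(w)
  # crack-count perimeter: mask/background transitions in 4-neighbourhood,
  # counting the frame border as background
  b <- matrix(0, nrow(mask), ncol(mask)); b[mask] <- 1
  cracks <- sum(abs(diff(rbind(0, b, 0)))) + sum(abs(diff(t(cbind(0, b, 0)))))
  perimeter <- cracks * pi / 4
  if (area == 1) {
    return(setNames(c(1, 0, 0, 0, 1), shape_feature_names))
  }
  mu_rr <- mean((w[, 1] - mean(w[, 1]))^2)
  mu_cc <- mean((w[, 2] - mean(w[, 2]))^2)
  mu_rc <- mean((w[, 1] - mean(w[, 1])) * (w[, 2] - mean(w[, 2])))
  common <- sqrt((mu_rr - mu_cc)^2 + 4 * mu_rc^2)
  l1 <- (mu_rr + mu_cc + common) / 2
  l2 <- (mu_rr + mu_cc - common) / 2
  l2 <- max(l2, 0)
  major <- 4 * sqrt(l1)
  minor <- 4 * sqrt(l2)
  ecc <- if (l1 > 0) sqrt(1 - l2 / l1) else 0
  roundness <- min(4 * pi * area / perimeter^2, 1)
  setNames(c(area, ecc, major, minor, roundness), shape_feature_names)
}

#' Full morphometric feature vector
#'
#' @param image Intensity matrix (crop).
#' @param mask Logical mask; for patches pass `NULL` (all pixels).
#' @param kind `"nucleus"` (104 features: shape + texture) or `"patch"`
#'   (99 features: texture only).
#' @return Named numeric vector.
#' @export
morphometric_features <- function(image, mask = NULL,
                                  kind = c("nucleus", "patch")) {
  kind <- match.arg(kind)
  if (kind == "nucleus") {
    if (is.null(mask)) abort("a nucleus feature vector needs a mask")
    c(shape_features(mask), texture_features(image, mask))
  } else {
    texture_features(image, mask)
  }
}

#' Names of the assembled feature columns
#'
#' @inheritParams morphometric_features
#' @return Character vector of length 104 (`"nucleus"`) or 99 (`"patch"`).
#' @export
feature_names <- function(kind = c("nucleus", "patch")) {
  kind <- match.arg(kind)
  tex <- c(sprintf("lbp_r%d_b%02d", rep(c(2, 3), each = 10), rep(0:9, 2)),
           as.vector(outer(0:8, 1:3, function(n, r)
             sprintf("pftas_img_t%d_n%d", r, n))),
           as.vector(outer(0:8, 1:3, function(n, r)
             sprintf("pftas_inv_t%d_n%d", r, n))),
           unlist(lapply(0:8, function(n)
             sprintf("zernike_n%d_m%d", n, seq(n %% 2, n, by = 2)))))
  if (kind == "nucleus") c(shape_feature_names, tex) else tex
}

#' Assemble a feature matrix for nuclei or patches
#'
#' Computes the morphometric vector for every element of a homogeneous list
#' of nucleus records or patches and returns them as a tibble: identifier
#' columns first, then 104 (nuclei) or 99 (patch) feature columns with
#' stable, documented names. An empty input yields a 0-row tibble with the
#' full header.
#'
#' @param x List of nucleus records (`nm_nucleus`) or patches (`nm_patch`).
#' @return Tibble of features.
#' @export
assemble_features <- function(x) {
  is_nuc <- vapply(x, inherits, TRUE, "nm_nucleus")
  is_patch <- vapply(x, inherits, TRUE, "nm_patch")
  if (length(x) && any(is_nuc) && any(is_patch)) {
    abort("mixed nucleus and patch inputs; assemble them separately")
  }
  if (length(x) && !all(is_nuc) && !all(is_patch)) {
    abort("inputs must all be nucleus records or all patches")
  }
  kind <- if (!length(x) || all(is_nuc)) "nucleus" else "patch"
  if (!length(x)) {
    hdr <- c(list(nucleus_id = integer(), class_label = character()),
             lapply(setNames(nm = feature_names(kind)), function(n) double()))
    return(as_tibble(hdr))
  }
  if (kind == "nucleus") {
    rows <- lapply(x, function(r) {
      fv <- morphometric_features(r$crop, r$mask, "nucleus")
      as_tibble(c(list(nucleus_id = r$id, class_label = r$class_label),
                  as.list(fv)))
    })
  } else {
    rows <- lapply(x, function(p) {
      fv <- morphometric_features(p$pixels, NULL, "patch")
      as_tibble(c(list(parent_id = p$parent_id,
                       offset_r = p$offset[1], offset_c = p$offset[2]),
                  as.list(fv)))
    })
  }
  bind_rows(rows)
}

#' Extract the numeric feature matrix from an assembled tibble
#'
#' @param tbl Output of [assemble_features()].
#' @return Numeric matrix of the feature columns only.
#' @export
feature_matrix <- function(tbl) {
  keep <- grepl("^(shape|lbp|pftas|zernike)_", names(tbl))
  as.matrix(tbl[, keep, drop = FALSE])
}
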