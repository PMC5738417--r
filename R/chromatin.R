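# Chromatin condensation statistic: heterochromatin / euchromatin (HC/EC)
# intensity ratio per nucleus.
#
# Heterochromatin is the above-threshold portion of the nuclear intensity,
# with the threshold placed a fixed 60% of the way between the dimmest and
# brightest nuclear pixel; euchromatin is the remainder of the total
# intensity. Minimum and maximum are taken over mask pixels only.

HC_COEF <- 0.6

#' Identify the nucleus by Otsu thresholding
#'
#' Thresholds the image with Otsu's method (256-bin histogram) and keeps the
#' largest connected component above the threshold, filling internal holes.
#' Used when a nucleus image arrives without a segmentation mask.
#'
#' @param image Numeric matrix of intensities.
#' @return Logical mask.
#' @export
otsu_nucleus_mask <- function(image) {
  if (length(unique(as.vector(image))) < 2) {
    abort("constant image: no threshold separates nucleus from background",
          class = "nm_degenerate_input")
  }
  thr <- otsu_threshold(as.vector(image))
  mask <- largest_component(image > thr)
  EBImage::fillHull(matrix(as.numeric(mask), nrow(mask), ncol(mask))) > 0
}

#' Heterochromatin intensity threshold
#'
#' `min + 0.6 * (max - min)` over the nuclear pixels.
#'
#' @param pixels Numeric vector of nuclear pixel intensities.
#' @return Threshold on the intensity scale.
#' @export
hc_threshold <- function(pixels) {
  if (length(pixels) == 0) abort("empty pixel set", class = "nm_degenerate_input")
  mn <- min(pixels); mx <- max(pixels)
  mn + HC_COEF * (mx - mn)
}

#' Chromatin condensation statistics for one nucleus
#'
#' Computes the heterochromatin threshold ([hc_threshold()]), the summed
#' intensity of pixels at or above it (HC), the remaining nuclear intensity
#' (EC = total - HC), and the condensation ratio HC/EC. HC + EC equals the
#' total mask intensity exactly, and the ratio is invariant to a positive
#' rescaling of the image.
#'
#' @param image Numeric matrix of intensities (a nucleus crop).
#' @param mask Logical mask of nuclear pixels; if `NULL`, derived with
#'   [otsu_nucleus_mask()].
#' @return Tibble with one row: `threshold`, `hc`, `ec`, `ratio`.
#' @examples
#' img <- matrix(c(10, 20, 100, 100), 2)
#' chromatin_stats(img, matrix(TRUE, 2, 2))  # threshold 64, HC 200, EC 30
#' @export
chromatin_stats <- function(image, mask = NULL) {
  if (is.null(mask)) mask <- otsu_nucleus_mask(image)
  if (!any(mask)) abort("empty mask", class = "nm_degenerate_input")
  px <- image[mask]
  thr <- hc_threshold(px)
  hc <- sum(px[px >= thr])
  total <- sum(px)
  ec <- total - hc
  if (ec == 0) {
    abort("all nuclear intensity above the heterochromatin threshold (EC = 0)",
          class = "nm_degenerate_input")
  }
  tibble(threshold = thr, hc = hc, ec = ec, ratio = hc / ec)
}

#' HC/EC table for a batch of nuclei
#'
#' @param records List of nucleus records (from [segment_field()] or
#'   [synth_nuclei()]).
#' @return Tibble with one row per nucleus: `nucleus_id`, `class_label`,
#'   `set_id`, `threshold`, `hc`, `ec`, `ratio`.
#' @export
chromatin_table <- function(records) {
  bind_rows(lapply(records, function(r) {
    st <- chromatin_stats(r$crop, r$mask)
    tibble(nucleus_id = r$id, class_label = r$class_label,
           set_id = r$set_id, !!!st)
  }))
}

#' Compare HC/EC ratios between two groups
#'
#' Two-sided unpaired Student's t-test on per-nucleus condensation ratios.
#'
#' @param ratios_a,ratios_b Numeric vectors of HC/EC ratios (n >= 2 each).
#' @return Tibble: `estimate_a`, `estimate_b`, `statistic`, `p_value`,
#'   `df`, `conf_low`, `conf_high`.
#' @export
group_compare <- function(ratios_a, ratios_b) {
  if (length(ratios_a) < 2 || length(ratios_b) < 2) {
    abort("each group needs at least two ratios")
  }
  tt <- t.test(ratios_a, ratios_b, var.equal = FALSE)
  tibble(estimate_a = mean(ratios_a), estimate_b = mean(ratios_b),
         statistic = unname(tt$statistic), p_value = tt$p.value,
         df = unname(tt$parameter),
         conf_low = tt$conf.int[1], conf_high = tt$conf.int[2])
}
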