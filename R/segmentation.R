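# Nucleus segmentation from 512x512 fields.
#
# Cultured-cell fields follow a 4-step procedure: (1) grayscale
# opening-by-reconstruction to regularise intensities and improve nucleus
# separation, (2) Sobel edge detection, (3) marker construction -- filled
# edge regions, split on the distance transform and shrunk to interior
# seeds, are foreground; pixels within the lowest 1% of frame values are
# background -- and (4) marker-based watershed (seeded region growing on
# the reconstructed image via EBImage::propagate). Quality filters then
# remove oversize (>128 px bounding box) and overexposed nuclei and trim a
# 15-px band from nuclei touching the frame border.
#
# Tissue fields use the alternative route: Shanbhag (dark-background)
# auto-threshold, Gaussian blur of the selection, re-binarisation, and
# watershed on the distance transform.

OVEREXP_LEVEL <- 3700
OVEREXP_FRAC <- 0.25
SIZE_CAP <- 128L
EDGE_TRIM <- 15L

#' Overexposure test for a nucleus
#'
#' A nucleus is overexposed when at least 25% of its pixels exceed 3700
#' counts (strict `> 3700`; the fraction comparison is inclusive).
#'
#' @param pixels_in_mask Numeric vector of the nucleus' pixel values.
#' @return Logical flag.
#' @export
is_overexposed <- function(pixels_in_mask) {
  if (length(pixels_in_mask) == 0) {
    abort("empty mask", class = "nm_degenerate_input")
  }
  mean(pixels_in_mask > OVEREXP_LEVEL) >= OVEREXP_FRAC
}

# Build a centred 128x128 record from a full-frame mask.
record_from_mask <- function(px, mask, id, field, edge_trimmed = FALSE,
                             canvas = SIZE_CAP) {
  bb <- mask_bbox(mask)
  h <- bb[2] - bb[1] + 1L; w <- bb[4] - bb[3] + 1L
  crop <- matrix(0L, canvas, canvas)
  mcan <- matrix(FALSE, canvas, canvas)
  r0 <- (canvas - h) %/% 2L; c0 <- (canvas - w) %/% 2L
  sub_m <- mask[bb[1]:bb[2], bb[3]:bb[4], drop = FALSE]
  sub_p <- px[bb[1]:bb[2], bb[3]:bb[4], drop = FALSE]
  sub_p[!sub_m] <- 0L
  crop[r0 + seq_len(h), c0 + seq_len(w)] <- sub_p
  mcan[r0 + seq_len(h), c0 + seq_len(w)] <- sub_m
  new_record(crop = crop, mask = mcan, id = id, bbox = bb,
             class_label = field$class_label, set_id = field$set_id,
             qc = list(overexposed = FALSE, oversize = FALSE,
                       edge_trimmed = edge_trimmed))
}

#' Trim the blurred border band from an edge nucleus
#'
#' Deconvolution blurs nuclei that touch the frame border; the 15 pixels of
#' the mask nearest each touched border are removed. If less than half of
#' the mask survives, the nucleus is dropped (`NULL`).
#'
#' @param mask Full-frame logical mask.
#' @param frame_shape `c(rows, cols)` of the frame.
#' @return List `(mask, trimmed)` or `NULL` when the remnant is too small.
#' @export
trim_edge_mask <- function(mask, frame_shape) {
  bb <- mask_bbox(mask)
  touched <- c(top = bb[1] == 1L, bottom = bb[2] == frame_shape[1],
               left = bb[3] == 1L, right = bb[4] == frame_shape[2])
  if (!any(touched)) return(list(mask = mask, trimmed = FALSE))
  n0 <- sum(mask)
  if (touched["top"])    mask[bb[1]:min(bb[1] + EDGE_TRIM - 1L, nrow(mask)), ] <- FALSE
  if (touched["bottom"]) mask[max(bb[2] - EDGE_TRIM + 1L, 1L):bb[2], ] <- FALSE
  if (touched["left"])   mask[, bb[3]:min(bb[3] + EDGE_TRIM - 1L, ncol(mask))] <- FALSE
  if (touched["right"])  mask[, max(bb[4] - EDGE_TRIM + 1L, 1L):bb[4]] <- FALSE
  if (sum(mask) < 0.5 * n0 || !any(mask)) return(NULL)
  list(mask = largest_component(mask), trimmed = TRUE)
}

# Shared QC + record construction for a label map.
records_from_labels <- function(lab, field, drop_filtered = TRUE) {
  px <- field$pixels
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  out <- list()
  for (id in ids) {
    mask <- lab == id
    mask <- largest_component(mask)
    if (sum(mask) < 50) next  # speckle
    bb <- mask_bbox(mask)
    oversize <- (bb[2] - bb[1] + 1L) > SIZE_CAP || (bb[4] - bb[3] + 1L) > SIZE_CAP
    overexp <- is_overexposed(px[mask])
    if ((oversize || overexp) && drop_filtered) next
    trimmed <- FALSE
    if (!oversize && !overexp) {
      tr <- trim_edge_mask(mask, dim(px))
      if (is.null(tr)) next
      mask <- tr$mask; trimmed <- tr$trimmed
    }
    bb2 <- mask_bbox(mask)
    canvas <- max(SIZE_CAP, bb2[2] - bb2[1] + 1L, bb2[4] - bb2[3] + 1L)
    rec <- record_from_mask(px, mask, length(out) + 1L, field,
                            edge_trimmed = trimmed, canvas = canvas)
    rec$qc$oversize <- oversize
    rec$qc$overexposed <- overexp
    out[[length(out) + 1L]] <- rec
  }
  out
}

#' Segment nuclei in a cultured-cell field
#'
#' Marker-based watershed segmentation with quality filtering (see the file
#' header for the full procedure). Returned records are 128x128-centred
#' crops (background zeroed outside the mask) that passed the size,
#' overexposure and edge filters; masks are pairwise disjoint.
#'
#' @param field An `nm_field` (or plain 512x512 matrix of counts).
#' @param drop_filtered Drop nuclei failing the oversize/overexposure
#'   filters (default). When `FALSE`, they are returned with their `qc`
#'   flags set, which is useful for auditing.
#' @return List of nucleus records (possibly empty).
#' @export
segment_field <- function(field, drop_filtered = TRUE) {
  if (is.matrix(field)) field <- new_field(field)
  px <- field$pixels
  v <- as.numeric(px)

  # blank-field early exit: nothing above the dim-background regime
  if (diff(range(v)) < 50) return(list())

  # 1. opening-by-reconstruction (disk ~10 px, i.e. ~2 um)
  rec <- gray_reconstruct(gray_erode(px * 1.0, 10L), px * 1.0)

  # 2. Sobel edges on the reconstructed image
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- EBImage::filter2(rec, kx, boundary = "replicate")
  gy <- EBImage::filter2(rec, t(kx), boundary = "replicate")
  grad <- sqrt(gx^2 + gy^2)

  # 3. markers: filled edge-enclosed regions, split on the distance
  #    transform, shrunk to interior seeds; background = lowest 1% of values
  edges <- grad > otsu_threshold(as.vector(grad))
  cand <- EBImage::fillHull(matrix(as.numeric(edges), nrow(px), ncol(px))) > 0
  dm <- EBImage::distmap(matrix(as.numeric(cand), nrow(px), ncol(px)))
  split_lab <- EBImage::watershed(dm, tolerance = 2)
  seeds <- split_lab
  seeds[dm <= 5] <- 0L  # erode to interior seeds
  n_seeds <- length(setdiff(unique(as.vector(seeds)), 0L))
  if (n_seeds == 0) return(list())
  # relabel seeds 1..n
  ids <- setdiff(sort(unique(as.vector(seeds))), 0L)
  seeds <- matrix(match(seeds, ids, nomatch = 0L), nrow(px), ncol(px))
  bg_label <- n_seeds + 1L
  bg <- v <= quantile(v, 0.01)
  seeds[matrix(bg, nrow(px), ncol(px)) & seeds == 0L] <- bg_label

  # 4. marker-based watershed (seeded region growing on the reconstruction)
  ws <- EBImage::propagate(rec / MAX_COUNT, seeds)
  ws[ws == bg_label] <- 0L
  # restrict basins to the bright candidate support
  ws[!cand] <- 0L

  records_from_labels(ws, field, drop_filtered = drop_filtered)
}

#' Shanbhag automatic threshold
#'
#' Fuzzy-entropy threshold of Shanbhag (1994) as implemented in ImageJ's
#' auto-threshold plugin, computed on a 256-bin histogram. With the
#' dark-background convention the nuclei are the above-threshold pixels.
#'
#' @param v Numeric vector of intensities.
#' @param levels Number of histogram bins (256, the 8-bit convention).
#' @return Threshold on the intensity scale.
#' @export
shanbhag_threshold <- function(v, levels = 256L) {
  r <- range(v)
  if (r[1] == r[2]) abort("cannot threshold a constant image")
  data <- tabulate(pmin(as.integer((v - r[1]) / (r[2] - r[1]) * (levels - 1L)) + 1L,
                        levels), nbins = levels)
  norm_histo <- data / sum(data)
  P1 <- cumsum(norm_histo)
  P2 <- 1 - P1
  first_bin <- match(TRUE, P1 > 0)
  last_bin <- levels + 1L - match(TRUE, rev(P2) > 0)
  threshold <- -1L; min_dist <- Inf
  for (it in first_bin:last_bin) {
    ent_back <- 0; term <- 0.5 / P1[it]
    if (it > 1) for (ih in 2:it) ent_back <- ent_back - norm_histo[ih] * log(1 - term * P1[ih - 1])
    ent_back <- ent_back * term
    ent_obj <- 0; term <- 0.5 / P2[it]
    if (it < levels) for (ih in (it + 1):levels) ent_obj <- ent_obj - norm_histo[ih] * log(1 - term * P2[ih])
    ent_obj <- ent_obj * term
    tot_ent <- abs(ent_back - ent_obj)
    if (tot_ent < min_dist) { min_dist <- tot_ent; threshold <- it }
  }
  r[1] + (threshold - 0.5) / (levels - 1L) * (r[2] - r[1])
}

#' Segment nuclei in a tissue-slice field
#'
#' Shanbhag (dark-background) auto-threshold, Gaussian blur of the selected
#' regions, re-binarisation, and watershed on the distance transform to
#' separate crowded nuclei. Records pass through the same quality filters
#' as [segment_field()].
#'
#' @inheritParams segment_field
#' @param blur_sigma Gaussian blur applied to the selection, px.
#' @return List of nucleus records.
#' @export
segment_tissue_field <- function(field, blur_sigma = 2,
                                 drop_filtered = TRUE) {
  if (is.matrix(field)) field <- new_field(field)
  px <- field$pixels
  v <- as.numeric(px)
  if (diff(range(v)) < 50) return(list())
  thr <- shanbhag_threshold(v)
  sel <- matrix(as.numeric(px > thr), nrow(px), ncol(px))
  sm <- EBImage::gblur(sel, sigma = blur_sigma, boundary = "replicate")
  bin <- sm > 0.5
  if (!any(bin)) return(list())
  dm <- EBImage::distmap(matrix(as.numeric(bin), nrow(px), ncol(px)))
  lab <- EBImage::watershed(dm, tolerance = 1)
  records_from_labels(lab, field, drop_filtered = drop_filtered)
}
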