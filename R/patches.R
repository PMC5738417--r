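# Patch extraction from nucleus crops.
#
# Sliding-window patches feed the patch-scale classifiers; marker-centred
# patches support conditioning the analysis on annotated foci (e.g.
# centromeric marks supplied as coordinates from a second channel).

new_patch <- function(pixels, parent_id, offset, coverage, kind = "lattice") {
  structure(list(pixels = pixels, parent_id = parent_id, offset = offset,
                 coverage = coverage, kind = kind),
            class = "nm_patch")
}

patch_overexposed <- function(pixels, frac = 0.25, level = 3700) {
  mean(pixels > level) >= frac
}

#' Extract sliding-window patches from a nucleus crop
#'
#' Enumerates the full stride lattice over the crop canvas and keeps patches
#' that (a) consist of at least `min_coverage` nucleus (fraction of patch
#' pixels inside the mask) and (b) are not overexposed, judged by the same
#' rule as whole nuclei (at least 25% of patch pixels above 3700 counts).
#'
#' @param record Nucleus record (`crop` + `mask` on a square canvas).
#' @param size Patch side, px (default 32).
#' @param stride Lattice stride, px (default 16).
#' @param min_coverage Minimum nucleus fraction per patch (default 0.85).
#' @param filter_overexposed Apply the patch overexposure filter
#'   (default TRUE).
#' @return List of patches; each has `pixels`, `parent_id`,
#'   `offset` (top-left, 1-based row/col) and `coverage`.
#' @examples
#' rec <- synth_nucleus(preset_classes()$open, seed = 1)
#' length(extract_patches(rec))
#' @export
extract_patches <- function(record, size = 32L, stride = 16L,
                            min_coverage = 0.85, filter_overexposed = TRUE) {
  canvas <- nrow(record$crop)
  size <- as.integer(size); stride <- as.integer(stride)
  if (size > canvas) abort("patch size exceeds the crop canvas")
  offs <- seq(1L, canvas - size + 1L, by = stride)
  out <- list()
  for (r0 in offs) for (c0 in offs) {
    rows <- r0:(r0 + size - 1L); cols <- c0:(c0 + size - 1L)
    cov <- mean(record$mask[rows, cols])
    if (cov < min_coverage) next
    px <- record$crop[rows, cols]
    if (filter_overexposed && patch_overexposed(px)) next
    out[[length(out) + 1L]] <- new_patch(px, record$id, c(r0, c0), cov)
  }
  out
}

patches_overlap <- function(off_a, off_b, size_a, size_b) {
  off_a[1] < off_b[1] + size_b && off_b[1] < off_a[1] + size_a &&
    off_a[2] < off_b[2] + size_b && off_b[2] < off_a[2] + size_a
}

#' Extract marker-centred patches and their complement
#'
#' Cuts a patch of side `size` around each marker coordinate (odd sizes
#' centre exactly on the coordinate; even sizes place it at index
#' `floor(size/2) + 1`), plus the complement set: all stride-lattice patches
#' of the same size that do not overlap any marker patch. Both sets pass the
#' coverage filter; markers outside the mask are skipped with a warning.
#'
#' @param record Nucleus record.
#' @param centers Matrix or data frame of marker (row, col) coordinates in
#'   crop coordinates.
#' @param size Patch side, px (default 11).
#' @param stride Stride for the complement lattice (default `size`).
#' @param min_coverage Minimum nucleus fraction per patch.
#' @return List with `marker` and `complement` patch lists.
#' @export
extract_marker_patches <- function(record, centers, size = 11L,
                                   stride = size, min_coverage = 0.85) {
  canvas <- nrow(record$crop)
  size <- as.integer(size)
  centers <- as.matrix(centers)
  half <- size %/% 2L
  marker <- list()
  if (nrow(centers)) {
    for (i in seq_len(nrow(centers))) {
      rc <- as.integer(centers[i, 1:2])
      if (rc[1] < 1 || rc[1] > canvas || rc[2] < 1 || rc[2] > canvas ||
          !record$mask[rc[1], rc[2]]) {
        warn(sprintf("marker %d at (%d, %d) lies outside the nucleus mask; skipped",
                     i, rc[1], rc[2]))
        next
      }
      r0 <- rc[1] - half; c0 <- rc[2] - half
      if (r0 < 1 || c0 < 1 || r0 + size - 1L > canvas || c0 + size - 1L > canvas) {
        warn(sprintf("marker %d too close to the canvas border; skipped", i))
        next
      }
      rows <- r0:(r0 + size - 1L); cols <- c0:(c0 + size - 1L)
      cov <- mean(record$mask[rows, cols])
      if (cov < min_coverage) next
      marker[[length(marker) + 1L]] <-
        new_patch(record$crop[rows, cols], record$id, c(r0, c0), cov,
                  kind = "marker")
    }
  }
  lattice <- extract_patches(record, size = size, stride = stride,
                             min_coverage = min_coverage)
  if (length(marker)) {
    keep <- vapply(lattice, function(p) {
      !any(vapply(marker, function(m)
        patches_overlap(p$offset, m$offset, size, size), TRUE))
    }, TRUE)
    lattice <- lattice[keep]
  }
  for (i in seq_along(lattice)) lattice[[i]]$kind <- "complement"
  list(marker = marker, complement = lattice)
}

#' Summarise a patch list as a tibble
#'
#' @param patches List of patches.
#' @return Tibble: `parent_id`, `offset_r`, `offset_c`, `coverage`, `kind`.
#' @export
patches_table <- function(patches) {
  bind_rows(lapply(patches, function(p) {
    tibble(parent_id = p$parent_id, offset_r = p$offset[1],
           offset_c = p$offset[2], coverage = p$coverage, kind = p$kind)
  }))
}
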