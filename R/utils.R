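# Shared internal helpers.
#
# All images in the package are plain numeric matrices holding 12-bit counts
# (0..4095), indexed [row, col]. EBImage is called with the same matrices;
# its x/y convention does not matter as long as it is used consistently.

MAX_COUNT <- 4095

clip12 <- function(x) pmin(pmax(x, 0), MAX_COUNT)

#' @noRd
assert_field_matrix <- function(px, arg = "pixels") {
  if (!is.matrix(px) || !is.numeric(px)) {
    abort(sprintf("`%s` must be a numeric matrix", arg))
  }
  if (any(px < 0) || any(px > MAX_COUNT)) {
    abort(sprintf("`%s` must lie in [0, %d] (12-bit counts)", arg, MAX_COUNT))
  }
  invisible(px)
}

# Deterministic per-item seed derived from a master seed. Kept below 2^31.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 7919) %% 2147483647)
}

# 3x3 grayscale min/max filters via shifted pmin/pmax (replicated borders).
shift_mat <- function(x, dr, dc) {
  nr <- nrow(x); nc <- ncol(x)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  x[ri, ci, drop = FALSE]
}

gray_erode3 <- function(x) {
  out <- x
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- pmin(out, shift_mat(x, dr, dc))
  }
  out
}

gray_dilate3 <- function(x) {
  out <- x
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- pmax(out, shift_mat(x, dr, dc))
  }
  out
}

# n iterations of the 3x3 filter approximate a disk of radius n.
gray_erode <- function(x, radius) {
  cpp_erode_disk(x, as.integer(radius))
}

gray_dilate <- function(x, radius) {
  for (i in seq_len(radius)) x <- gray_dilate3(x)
  x
}

# Grayscale morphological reconstruction by dilation of `marker` under
# `mask` (geodesic; compiled hybrid algorithm).
gray_reconstruct <- function(marker, mask) {
  cpp_reconstruct_dilation(marker, mask)
}

# Otsu threshold on integer counts; returns the threshold on the count scale.
otsu_threshold <- function(v, levels = 256L) {
  r <- range(v)
  if (r[1] == r[2]) abort("cannot threshold a constant image")
  h <- tabulate(pmin(as.integer((v - r[1]) / (r[2] - r[1]) * (levels - 1L)) + 1L,
                     levels), nbins = levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(levels))
  mu_t <- mu[levels]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  r[1] + (k - 0.5) / (levels - 1L) * (r[2] - r[1])
}

# Connected components of a logical matrix (8-connectivity), via EBImage.
label_components <- function(mask) {
  EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
}

largest_component <- function(mask) {
  lab <- label_components(mask)
  n <- max(lab)
  if (n == 0) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0], nbins = n)
  lab == which.max(sizes)
}

jaccard <- function(a, b) {
  sum(a & b) / sum(a | b)
}

mask_bbox <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  c(min(w[, 1]), max(w[, 1]), min(w[, 2]), max(w[, 2]))
}
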