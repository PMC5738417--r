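# Texture feature blocks: local binary patterns (LBP), parameter-free
# threshold adjacency statistics (PFTAS), and Zernike moment magnitudes.
#
# No installed R package provides these descriptors, so they are
# implemented here from their published definitions: rotation-invariant
# uniform LBP (Ojala et al. 2002), PFTAS (Hamilton et al. 2007; 54 values:
# 9-bin adjacency histograms at three automatic thresholds on the image and
# its complement), and Zernike magnitudes up to degree 8 (25 values) over
# the mask's enclosing circle.

# zero-filled shift (for adjacency counts)
shift0 <- function(x, dr, dc) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- x[rs - dr, cs - dc, drop = FALSE]
  out
}

bilinear_at <- function(image, r, c) {
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  # clamp the +1 indices: at an exact-integer coordinate the clamped cell
  # carries zero weight, so values are unaffected
  r1 <- pmin(r0 + 1, nrow(image)); c1 <- pmin(c0 + 1, ncol(image))
  r0 <- pmax(r0, 1); c0 <- pmax(c0, 1)
  i00 <- cbind(r0, c0); i01 <- cbind(r0, c1)
  i10 <- cbind(r1, c0); i11 <- cbind(r1, c1)
  image[i00] * (1 - fr) * (1 - fc) + image[i01] * (1 - fr) * fc +
    image[i10] * fr * (1 - fc) + image[i11] * fr * fc
}

lbp_riu2_hist <- function(image, mask, radius, n_points = 8L) {
  m <- ceiling(radius)
  nr <- nrow(image); nc <- ncol(image)
  if (nr < 2 * m + 1 || nc < 2 * m + 1) {
    abort("mask smaller than the LBP neighbourhood", class = "nm_degenerate_input")
  }
  interior <- matrix(FALSE, nr, nc)
  interior[(m + 1):(nr - m), (m + 1):(nc - m)] <- TRUE
  centers <- which(mask & interior, arr.ind = TRUE)
  if (nrow(centers) == 0) {
    abort("mask smaller than the LBP neighbourhood", class = "nm_degenerate_input")
  }
  gc_ <- image[centers]
  bits <- matrix(FALSE, nrow(centers), n_points)
  for (k in seq_len(n_points)) {
    ang <- 2 * pi * (k - 1) / n_points
    dr <- -radius * sin(ang); dc <- radius * cos(ang)
    gk <- bilinear_at(image, centers[, 1] + dr, centers[, 2] + dc)
    # small absolute tolerance so exact ties survive interpolation rounding
    bits[, k] <- gk >= gc_ - 1e-6
  }
  trans <- rowSums(bits != bits[, c(2:n_points, 1), drop = FALSE])
  lab <- ifelse(trans <= 2, rowSums(bits), n_points + 1L)
  h <- tabulate(lab + 1L, nbins = n_points + 2L)  # 0..8 uniform + nonuniform
  h
}

lbp_features <- function(image, mask, radii = c(2, 3)) {
  h <- unlist(lapply(radii, function(r) lbp_riu2_hist(image, mask, r)))
  v <- h / sum(h)
  names(v) <- unlist(lapply(radii, function(r)
    sprintf("lbp_r%d_b%02d", r, 0:9)))
  v
}

tas_hist <- function(image, mask, lo, hi) {
  b <- matrix(0, nrow(image), ncol(image))
  b[mask & image >= lo & image <= hi] <- 1
  cnt <- matrix(0, nrow(image), ncol(image))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    cnt <- cnt + shift0(b, dr, dc)
  }
  on <- b == 1
  if (!any(on)) return(rep(0, 9))
  h <- tabulate(cnt[on] + 1L, nbins = 9L)
  h / sum(h)
}

pftas_half <- function(image, mask, tag) {
  v <- image[mask]
  thr <- tryCatch(otsu_threshold(v), error = function(e) mean(v))
  sel <- v > thr
  if (!any(sel)) sel <- rep(TRUE, length(v))
  mu <- mean(v[sel])
  sig <- stats::sd(v[sel])
  if (!is.finite(sig)) sig <- 0
  ranges <- list(c(mu - sig, mu + sig), c(mu - sig, Inf), c(mu, Inf))
  out <- unlist(lapply(seq_along(ranges), function(i)
    tas_hist(image, mask, ranges[[i]][1], ranges[[i]][2])))
  names(out) <- as.vector(outer(0:8, 1:3, function(n, r)
    sprintf("pftas_%s_t%d_n%d", tag, r, n)))
  out
}

pftas_features <- function(image, mask) {
  mx <- max(image[mask])
  c(pftas_half(image, mask, "img"),
    pftas_half(mx - image, mask, "inv"))
}

zernike_radial <- function(n, m, rho) {
  s_max <- (n - m) / 2
  out <- 0
  for (s in 0:s_max) {
    coef <- (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + m) / 2 - s) * factorial((n - m) / 2 - s))
    out <- out + coef * rho^(n - 2 * s)
  }
  out
}

zernike_features <- function(image, mask, degree = 8L) {
  nm_pairs <- do.call(rbind, lapply(0:degree, function(n) {
    m <- seq(n %% 2, n, by = 2)
    cbind(n = rep(n, length(m)), m = m)
  }))
  nms <- sprintf("zernike_n%d_m%d", nm_pairs[, 1], nm_pairs[, 2])
  w <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(w)
  rad <- sqrt(max((w[, 1] - ctr[1])^2 + (w[, 2] - ctr[2])^2)) + 0.5
  all_idx <- which(matrix(TRUE, nrow(image), ncol(image)), arr.ind = TRUE)
  rho <- sqrt((all_idx[, 1] - ctr[1])^2 + (all_idx[, 2] - ctr[2])^2) / rad
  inside <- rho <= 1
  f <- as.vector(image * mask)[inside]
  tot <- sum(f)
  if (tot <= 0) return(setNames(rep(0, nrow(nm_pairs)), nms))
  f <- f / tot
  rho <- rho[inside]
  theta <- atan2(all_idx[inside, 1] - ctr[1], all_idx[inside, 2] - ctr[2])
  vals <- vapply(seq_len(nrow(nm_pairs)), function(i) {
    n <- nm_pairs[i, 1]; m <- nm_pairs[i, 2]
    rp <- zernike_radial(n, m, rho)
    re <- sum(f * rp * cos(m * theta))
    im <- sum(f * rp * sin(m * theta))
    (n + 1) / pi * sqrt(re^2 + im^2)
  }, 0)
  setNames(vals, nms)
}

#' Texture feature blocks for one nucleus or patch
#'
#' Concatenates rotation-invariant uniform LBP histograms (8 neighbours at
#' radii 2 and 3; 10 bins each, jointly normalised to sum 1), the 54
#' parameter-free threshold adjacency statistics, and the 25 Zernike moment
#' magnitudes up to degree 8 -- 99 values in total. LBP codes are computed
#' at mask pixels only; PFTAS thresholds derive from the masked intensities;
#' Zernike moments integrate the masked intensity over the mask's enclosing
#' circle.
#'
#' @param image Numeric intensity matrix.
#' @param mask Logical mask (same shape). Defaults to all pixels, the
#'   convention for patches that already passed the coverage filter.
#' @return Named numeric vector of length 99.
#' @export
texture_features <- function(image, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  if (!any(mask)) abort("empty mask", class = "nm_degenerate_input")
  c(lbp_features(image, mask),
    pftas_features(image, mask),
    zernike_features(image, mask))
}
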