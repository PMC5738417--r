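# Synthetic DAPI-like image generator.
#
# The generator exists so that segmentation, chromatin quantification,
# feature extraction and the classifiers can all be exercised against known
# ground truth. Nuclei are rendered as soft-edged ellipses of baseline
# (euchromatin) intensity carrying Gaussian heterochromatin foci; fields are
# 512x512 12-bit frames over a dim Gaussian background whose mean sits at
# ~1% of the dynamic range, so the lowest-1% background-marker rule used by
# the segmenter has support.

BG_MEAN <- 41   # ~1% of 4095
BG_SD <- 8

synth_background <- function(nr, nc, mean = BG_MEAN, sd = BG_SD) {
  clip12(matrix(rnorm(nr * nc, mean, sd), nr, nc))
}

#' Generate one synthetic nucleus
#'
#' Draws a single nucleus from a class specification: an elliptical mask
#' (area-equivalent radius and eccentricity sampled per spec), baseline
#' intensity plus per-pixel Gaussian noise, and Poisson-many heterochromatin
#' foci rendered as truncated Gaussian bumps peaking at
#' `base_intensity * foci_gain`. The mask boundary is softened by a 1-px
#' Gaussian so edges resemble band-limited microscope data. Identical
#' `(spec, seed)` give bit-identical output.
#'
#' @param spec A [class_spec()].
#' @param seed Integer seed.
#' @param canvas Side of the square crop canvas, px (default 128).
#' @return A nucleus record: list with integer `crop` (canvas x canvas,
#'   counts; background-level outside the mask), logical `mask`, `class_label`,
#'   `id`, `seed` and default `qc` flags.
#' @examples
#' nuc <- synth_nucleus(preset_classes()$condensed, seed = 1)
#' range(nuc$crop)
#' @export
synth_nucleus <- function(spec, seed, canvas = 128L) {
  stopifnot(inherits(spec, "nm_class_spec"))
  canvas <- as.integer(canvas)
  withr::local_seed(seed)

  r <- max(spec$nucleus_radius_px + rnorm(1, 0, spec$nucleus_radius_sd), 4)
  ecc <- runif(1, spec$eccentricity_range[1], spec$eccentricity_range[2])
  a <- r / (1 - ecc^2)^(1 / 4)   # semi-major; preserves area pi*r^2
  b <- r * (1 - ecc^2)^(1 / 4)
  if (a > canvas / 2 - 4) {
    abort(sprintf("nucleus radius too large for the %dx%d crop canvas",
                  canvas, canvas), class = "nm_parameter_error")
  }
  theta <- runif(1, 0, pi)

  ctr <- (canvas + 1) / 2
  rr <- matrix(seq_len(canvas) - ctr, canvas, canvas)
  cc <- t(rr)
  u <- cos(theta) * cc + sin(theta) * rr
  v <- -sin(theta) * cc + cos(theta) * rr
  mask <- (u / a)^2 + (v / b)^2 <= 1

  intensity <- matrix(spec$base_intensity, canvas, canvas)
  if (spec$intensity_noise_sd > 0) {
    intensity <- intensity + matrix(rnorm(canvas^2, 0, spec$intensity_noise_sd),
                                    canvas, canvas)
  }

  n_foci <- if (spec$foci_mean > 0) rpois(1, spec$foci_mean) else 0L
  foci_rc <- matrix(integer(), 0, 2, dimnames = list(NULL, c("row", "col")))
  if (n_foci > 0) {
    idx <- which(mask)
    centers <- idx[sample.int(length(idx), n_foci, replace = TRUE)]
    foci_rc <- cbind(row = (centers - 1L) %% canvas + 1L,
                     col = (centers - 1L) %/% canvas + 1L)
    sig <- spec$foci_radius_px / 2
    ext <- ceiling(3 * sig)
    amp <- spec$base_intensity * (spec$foci_gain - 1)
    off <- expand.grid(dr = -ext:ext, dc = -ext:ext)
    bump <- exp(-(off$dr^2 + off$dc^2) / (2 * sig^2))
    keep <- (off$dr^2 + off$dc^2) <= (3 * sig)^2
    # overlapping foci saturate (max-combine) rather than stack: focus
    # brightness is bounded by local chromatin density, so the brightest
    # pixel sits near base_intensity * foci_gain for any focus count
    g <- matrix(0, canvas, canvas)
    for (ci in centers) {
      r0 <- (ci - 1L) %% canvas + 1L
      c0 <- (ci - 1L) %/% canvas + 1L
      rs <- r0 + off$dr[keep]
      cs <- c0 + off$dc[keep]
      ok <- rs >= 1 & rs <= canvas & cs >= 1 & cs <= canvas
      ii <- cbind(rs[ok], cs[ok])
      g[ii] <- pmax(g[ii], bump[keep][ok])
    }
    intensity <- intensity + amp * g
  }

  # soften the boundary outward only: mask pixels keep pure nuclear signal
  # (so the within-mask minimum reflects the chromatin noise floor, as in
  # real DAPI data), while optical blur spreads signal a little beyond the
  # boundary into the background
  w <- EBImage::gblur(matrix(as.numeric(mask), canvas, canvas), sigma = 1,
                      boundary = 0)
  w <- pmin(pmax(w, 0), 1)
  w[mask] <- 1
  crop <- w * intensity + (1 - w) * synth_background(canvas, canvas)
  crop <- round(clip12(crop))
  storage.mode(crop) <- "integer"

  rec <- new_record(crop = crop, mask = mask, id = 1L,
                    class_label = spec$name, seed = seed)
  rec$foci <- foci_rc  # ground-truth focus centres (crop coordinates)
  rec
}

new_record <- function(crop, mask, id, class_label = NA_character_,
                       set_id = NA_character_, bbox = NULL, seed = NA_integer_,
                       qc = list(overexposed = FALSE, oversize = FALSE,
                                 edge_trimmed = FALSE)) {
  structure(list(crop = crop, mask = mask, id = id, bbox = bbox,
                 class_label = class_label, set_id = set_id, seed = seed,
                 qc = qc),
            class = "nm_nucleus")
}

#' @export
print.nm_nucleus <- function(x, ...) {
  cat(sprintf("<nm_nucleus> id %s (%s): %d px mask on %dx%d canvas",
              x$id, x$class_label, sum(x$mask), nrow(x$crop), ncol(x$crop)))
  flags <- names(Filter(isTRUE, x$qc))
  if (length(flags)) cat(" [", paste(flags, collapse = ", "), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Generate a batch of synthetic nuclei
#'
#' Convenience wrapper around [synth_nucleus()]: per-nucleus seeds are drawn
#' deterministically from the master seed (counter-based), so the batch is a
#' pure function of `(spec, n, seed)`.
#'
#' @inheritParams synth_nucleus
#' @param n Number of nuclei.
#' @param set_id Optional acquisition-set tag stored on each record.
#' @return List of nucleus records.
#' @export
synth_nuclei <- function(spec, n, seed, canvas = 128L, set_id = NA_character_) {
  lapply(seq_len(n), function(i) {
    rec <- synth_nucleus(spec, derive_seed(seed, i), canvas)
    rec$id <- i
    rec$set_id <- set_id
    rec
  })
}

#' Generate a synthetic 512x512 field with ground truth
#'
#' Places `n_nuclei` synthetic nuclei (classes cycled over `specs`) at
#' non-overlapping random positions on a dim-background frame, returning the
#' frame together with a per-pixel ground-truth label map. Placement retries
#' a bounded number of times and errors if the field cannot accommodate the
#' requested count.
#'
#' @param specs A [class_spec()] or list of them; nuclei cycle through them.
#' @param n_nuclei Number of nuclei to place (>= 0).
#' @param seed Integer seed.
#' @param width,height Frame size, px (default 512).
#' @param min_gap Minimum gap enforced between nucleus masks, px.
#' @param positions Optional n x 2 matrix of (row, col) centres overriding
#'   random placement (still subject to the overlap check).
#' @param bg_mean,bg_sd Background intensity model, counts. The defaults
#'   emulate clean glass-bottom-dish imaging (~1% of the dynamic range);
#'   tissue-slice fields are better emulated with a brighter, broader
#'   background (e.g. `bg_mean = 280, bg_sd = 110`) standing in for
#'   stromal/adipose autofluorescence.
#' @param set_id Acquisition-set tag stored on the field.
#' @return List with `field` (an `nm_field`), integer `labels` map
#'   (0 = background), `masks` (list of logical ground-truth masks) and a
#'   `truth` tibble (id, class, centre, per-nucleus seed).
#' @export
synth_field <- function(specs, n_nuclei, seed, width = 512L, height = 512L,
                        min_gap = 4L, positions = NULL,
                        bg_mean = BG_MEAN, bg_sd = BG_SD,
                        set_id = "synth") {
  if (inherits(specs, "nm_class_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, TRUE, "nm_class_spec")))
  if (n_nuclei < 0) abort("`n_nuclei` must be >= 0")
  withr::local_seed(derive_seed(seed, 0L))

  px <- synth_background(height, width, bg_mean, bg_sd)
  labels <- matrix(0L, height, width)
  masks <- list()
  truth <- list()

  for (i in seq_len(n_nuclei)) {
    spec <- specs[[(i - 1L) %% length(specs) + 1L]]
    nseed <- derive_seed(seed, i)
    nuc <- synth_nucleus(spec, nseed)
    canvas <- nrow(nuc$crop)
    placed <- FALSE
    n_try <- if (is.null(positions)) 300L else 1L
    for (try in seq_len(n_try)) {
      if (is.null(positions)) {
        r0 <- sample.int(height - canvas + 1L, 1L)
        c0 <- sample.int(width - canvas + 1L, 1L)
      } else {
        r0 <- as.integer(positions[i, 1]) - canvas %/% 2L
        c0 <- as.integer(positions[i, 2]) - canvas %/% 2L
        if (r0 < 1L || c0 < 1L || r0 + canvas - 1L > height ||
            c0 + canvas - 1L > width) {
          abort("supplied position places the nucleus outside the frame",
                class = "nm_placement_error")
        }
      }
      rows <- r0:(r0 + canvas - 1L)
      cols <- c0:(c0 + canvas - 1L)
      # overlap check on the dilated mask enforces the gap
      dil <- nuc$mask
      for (k in seq_len(min_gap)) dil <- gray_dilate3(dil) > 0
      if (!any(labels[rows, cols][dil] > 0)) {
        full_mask <- matrix(FALSE, height, width)
        full_mask[rows, cols] <- nuc$mask
        px[rows, cols][nuc$mask] <- nuc$crop[nuc$mask]
        labels[full_mask] <- i
        masks[[i]] <- full_mask
        truth[[i]] <- tibble(id = i, class = spec$name,
                             center_r = r0 + (canvas - 1) / 2,
                             center_c = c0 + (canvas - 1) / 2,
                             seed = nseed)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort(sprintf("could not place nucleus %d without overlap", i),
            class = "nm_placement_error")
    }
  }

  storage.mode(px) <- "integer"
  field <- new_field(px, set_id = set_id)
  list(field = field, labels = labels, masks = masks,
       truth = if (length(truth)) bind_rows(truth) else
         tibble(id = integer(), class = character(),
                center_r = double(), center_c = double(), seed = integer()))
}

#' Construct a field-image object
#'
#' @param pixels Numeric matrix of 12-bit counts.
#' @param set_id Acquisition-set tag.
#' @param class_label Optional class label for the whole field.
#' @param pixel_size_um Pixel size in micrometres.
#' @return An `nm_field`.
#' @export
new_field <- function(pixels, set_id = NA_character_,
                      class_label = NA_character_, pixel_size_um = 0.2150) {
  assert_field_matrix(pixels)
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, set_id = set_id, class_label = class_label,
                 pixel_size_um = pixel_size_um),
            class = "nm_field")
}

#' @export
print.nm_field <- function(x, ...) {
  cat(sprintf("<nm_field> %dx%d, set %s, range [%d, %d]\n",
              nrow(x$pixels), ncol(x$pixels), x$set_id,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

motion_kernel <- function(drift_vector) {
  dx <- drift_vector[1]; dy <- drift_vector[2]
  n <- max(abs(dx), abs(dy)) + 1L
  t <- seq(0, 1, length.out = n)
  pr <- round(t * dy); pc <- round(t * dx)
  hr <- max(abs(pr)); hc <- max(abs(pc))
  k <- matrix(0, 2L * hr + 1L, 2L * hc + 1L)
  for (i in seq_len(n)) {
    k[hr + pr[i] + 1L, hc + pc[i] + 1L] <- k[hr + pr[i] + 1L, hc + pc[i] + 1L] + 1
  }
  k / sum(k)
}

#' Corrupt a synthetic field with an acquisition-noise mode
#'
#' Applies one [noise_spec()] to a generated field: overexposure raises a
#' requested fraction of a nucleus' pixels above the 3700-count saturation
#' line; drift blur convolves the whole frame with a normalised linear
#' motion kernel (total intensity preserved up to boundary effects); edge
#' placement translates a nucleus so its mask intersects the frame border.
#' A no-op `noise_spec()` returns the input unchanged.
#'
#' @param fieldset Result of [synth_field()] (field + label map), or an
#'   `nm_field` for the drift-only case.
#' @param noise A [noise_spec()].
#' @param nuclei Integer ids of target nuclei for overexposure/edge modes
#'   (default: all).
#' @param seed Seed for the overexposed-pixel draw.
#' @return Object of the same shape as `fieldset`, with `labels`/`masks`
#'   kept consistent for the edge mode.
#' @export
apply_corruption <- function(fieldset, noise, nuclei = NULL, seed = 1L) {
  stopifnot(inherits(noise, "nm_noise_spec"))
  bare <- inherits(fieldset, "nm_field")
  if (bare) {
    if (noise$overexposure_fraction > 0 || noise$place_on_edge) {
      abort("overexposure/edge modes need the labelled result of synth_field()")
    }
    fieldset <- list(field = fieldset, labels = NULL, masks = NULL)
  }
  px <- fieldset$field$pixels
  labels <- fieldset$labels
  withr::local_seed(seed)

  if (noise$place_on_edge) {
    ids <- nuclei %||% sort(unique(labels[labels > 0]))
    for (id in ids) {
      m <- labels == id
      bb <- mask_bbox(m)
      shift <- -(bb[3] - 1L) - as.integer((bb[4] - bb[3]) * 0.4) # push left
      idx <- which(m, arr.ind = TRUE)
      vals <- px[idx]
      px[idx] <- round(synth_background(nrow(idx), 1))
      labels[idx] <- 0L
      nc2 <- idx[, 2] + shift
      ok <- nc2 >= 1L
      px[cbind(idx[ok, 1], nc2[ok])] <- vals[ok]
      labels[cbind(idx[ok, 1], nc2[ok])] <- id
      if (!is.null(fieldset$masks)) {
        fieldset$masks[[id]] <- labels == id
      }
    }
  }

  if (noise$overexposure_fraction > 0) {
    ids <- nuclei %||% sort(unique(labels[labels > 0]))
    for (id in ids) {
      idx <- which(labels == id)
      k <- ceiling(noise$overexposure_fraction * length(idx))
      hot <- idx[sample.int(length(idx), k)]
      px[hot] <- pmax(px[hot], 3900L)  # only ever raises values
    }
  }

  if (any(noise$drift_vector != 0L)) {
    k <- motion_kernel(noise$drift_vector)
    blurred <- EBImage::filter2(px, k, boundary = "replicate")
    px <- round(clip12(blurred))
  }

  storage.mode(px) <- "integer"
  fieldset$field$pixels <- px
  fieldset$labels <- labels
  if (bare) fieldset$field else fieldset
}
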