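# Shared fixtures and independent oracles, built in code at test time.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, expr, envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Reconstruct a record's mask in frame coordinates from its bbox.
record_frame_mask <- function(rec, frame_dim) {
  bb <- rec$bbox
  h <- bb[2] - bb[1] + 1L; w <- bb[4] - bb[3] + 1L
  can <- nrow(rec$mask)
  r0 <- (can - h) %/% 2L; c0 <- (can - w) %/% 2L
  mm <- matrix(FALSE, frame_dim[1], frame_dim[2])
  mm[bb[1]:bb[2], bb[3]:bb[4]] <- rec$mask[r0 + seq_len(h), c0 + seq_len(w)]
  mm
}

# Best ground-truth Jaccard for each segmented record.
best_jaccards <- function(records, gt_masks, frame_dim = c(512, 512)) {
  vapply(records, function(r) {
    mm <- record_frame_mask(r, frame_dim)
    max(vapply(gt_masks, function(g) sum(mm & g) / sum(mm | g), 0))
  }, 0)
}

# Independent brute-force patch enumeration oracle: loops over every
# lattice offset and applies the coverage and overexposure definitions
# directly.
brute_force_patch_count <- function(crop, mask, size = 32L, stride = 16L,
                                    min_coverage = 0.85,
                                    filter_overexposed = TRUE) {
  canvas <- nrow(crop)
  n <- 0L
  for (r0 in seq(1L, canvas - size + 1L, by = stride)) {
    for (c0 in seq(1L, canvas - size + 1L, by = stride)) {
      sub_m <- mask[r0:(r0 + size - 1L), c0:(c0 + size - 1L)]
      if (sum(sub_m) / size^2 < min_coverage) next
      sub_p <- crop[r0:(r0 + size - 1L), c0:(c0 + size - 1L)]
      if (filter_overexposed && mean(sub_p > 3700) >= 0.25) next
      n <- n + 1L
    }
  }
  n
}

# random blobby mask on a canvas (for property tests)
random_mask <- function(canvas = 128L, seed = 1L) {
  withr::local_seed(seed)
  ctr <- canvas / 2 + runif(2, -20, 20)
  a <- runif(1, 15, 55); b <- runif(1, 15, 55); th <- runif(1, 0, pi)
  rr <- matrix(seq_len(canvas) - ctr[1], canvas, canvas)
  cc <- matrix(rep(seq_len(canvas) - ctr[2], each = canvas), canvas, canvas)
  u <- cos(th) * cc + sin(th) * rr
  v <- -sin(th) * cc + cos(th) * rr
  (u / a)^2 + (v / b)^2 <= 1
}

two_class_nuclei <- function(n_per = 40L, seed = 7L) {
  cl <- preset_classes()
  list(open = synth_nuclei(cl$open, n_per, seed = seed, set_id = "open"),
       condensed = synth_nuclei(cl$condensed, n_per, seed = seed + 1000L,
                                set_id = "condensed"))
}
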