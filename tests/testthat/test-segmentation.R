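test_that("well-separated nuclei are recovered with high mask overlap", {
  fs <- fixture("field5", synth_field(preset_classes(), 5, seed = 31))
  recs <- segment_field(fs$field)
  expect_length(recs, 5)
  js <- best_jaccards(recs, fs$masks)
  expect_true(all(js >= 0.8))
  # pairwise disjoint output masks
  acc <- matrix(0L, 512, 512)
  for (r in recs) acc <- acc + record_frame_mask(r, c(512, 512))
  expect_true(all(acc <= 1))
  # crops: canvas bounded, background zeroed outside the mask
  for (r in recs) {
    expect_lte(nrow(r$crop), 128L)
    expect_true(all(r$crop[!r$mask] == 0))
    expect_equal(max(EBImage::bwlabel(r$mask * 1)), 1)
  }
})

test_that("a blank field yields no records from either segmentation path", {
  blank <- new_field(matrix(40L, 512, 512) +
                       matrix(as.integer(rbinom(512^2, 1, 0.1)), 512))
  expect_length(segment_field(blank), 0)
  expect_length(segment_tissue_field(blank), 0)
})

test_that("two touching nuclei are separated by the watershed", {
  spec <- class_spec("t", nucleus_radius_px = 20, nucleus_radius_sd = 0.5,
                     eccentricity_range = c(0, 0.1))
  fs <- synth_field(spec, 2, seed = 17, min_gap = 0L,
                    positions = rbind(c(256, 235), c(256, 277)))
  recs <- segment_field(fs$field)
  expect_length(recs, 2)
  expect_true(all(best_jaccards(recs, fs$masks) >= 0.7))
})

test_that("the overexposure rule matches its definition at the boundary", {
  px <- c(rep(4000, 30), rep(100, 70))
  expect_true(is_overexposed(px))
  expect_false(is_overexposed(c(rep(4000, 10), rep(100, 90))))
  # exactly 25% just above the line: 'at least 25%', strict '> 3700'
  expect_true(is_overexposed(c(rep(3701, 25), rep(100, 75))))
  expect_false(is_overexposed(c(rep(3700, 25), rep(100, 75))))
  expect_error(is_overexposed(numeric()), class = "nm_degenerate_input")
})

test_that("edge trimming removes 15-px bands and drops slivers", {
  frame <- c(512L, 512L)
  interior <- matrix(FALSE, 512, 512); interior[200:260, 200:260] <- TRUE
  tr <- trim_edge_mask(interior, frame)
  expect_identical(tr$mask, interior)
  expect_false(tr$trimmed)

  left <- matrix(FALSE, 512, 512); left[200:260, 1:60] <- TRUE
  tr <- trim_edge_mask(left, frame)
  expect_true(tr$trimmed)
  expect_identical(which(colSums(tr$mask) > 0), 16:60)
  # idempotence: a trimmed mask no longer touches the border
  tr2 <- trim_edge_mask(tr$mask, frame)
  expect_identical(tr2$mask, tr$mask)
  expect_false(tr2$trimmed)

  corner <- matrix(FALSE, 512, 512); corner[1:60, 1:60] <- TRUE
  trc <- trim_edge_mask(corner, frame)
  expect_identical(which(colSums(trc$mask) > 0), 16:60)
  expect_identical(which(rowSums(trc$mask) > 0), 16:60)

  sliver <- matrix(FALSE, 512, 512); sliver[200:260, 1:20] <- TRUE
  expect_null(trim_edge_mask(sliver, frame))
})

test_that("oversize nuclei are flagged and removed", {
  px <- matrix(40L, 512, 512)
  d <- sqrt(outer((1:512) - 250, rep(1, 512))^2 +
              outer(rep(1, 512), (1:512) - 250)^2)
  px[d <= 75] <- 2000L
  f <- new_field(px)
  kept <- segment_field(f)
  expect_length(kept, 0)
  all_recs <- segment_field(f, drop_filtered = FALSE)
  expect_true(any(vapply(all_recs, function(r) r$qc$oversize, TRUE)))
})

test_that("an overexposure-corrupted nucleus fails the downstream filter", {
  fs <- fixture("field5", synth_field(preset_classes(), 5, seed = 31))
  hot <- apply_corruption(fs, noise_spec(overexposure_fraction = 0.30),
                          nuclei = 1L)
  flagged <- segment_field(hot$field, drop_filtered = FALSE)
  expect_identical(sum(vapply(flagged, function(r) r$qc$overexposed, TRUE)), 1L)
  expect_length(segment_field(hot$field), 4)
})

test_that("tissue segmentation recovers most crowded nuclei", {
  # crowded large nuclei over a broad autofluorescent background, the
  # regime entropy thresholding is designed for
  spec <- class_spec("tissue", nucleus_radius_px = 32, nucleus_radius_sd = 2,
                     foci_gain = 1.3, foci_mean = 10)
  fs <- synth_field(spec, 8, seed = 41, min_gap = 2L,
                    bg_mean = 280, bg_sd = 110)
  recs <- segment_tissue_field(fs$field)
  js <- best_jaccards(recs, fs$masks)
  expect_gte(sum(js >= 0.6), 6)

  # an isolated nucleus is found once by both segmentation paths
  one <- synth_field(class_spec("s", nucleus_radius_px = 36,
                                nucleus_radius_sd = 1), 1, seed = 42,
                     width = 160L, height = 160L, bg_mean = 280, bg_sd = 110)
  expect_length(segment_field(one$field), 1)
  expect_length(segment_tissue_field(one$field), 1)
})

test_that("the Shanbhag threshold lies inside the data range", {
  withr::local_seed(13)
  v <- pmax(c(rnorm(30000, 300, 110), rnorm(10000, 1500, 150)), 0)
  thr <- shanbhag_threshold(v)
  expect_gt(thr, min(v))
  expect_lt(thr, max(v))
  expect_error(shanbhag_threshold(rep(5, 10)))
})
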