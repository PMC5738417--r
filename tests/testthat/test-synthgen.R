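test_that("a noise-free, focus-free spec yields a constant elliptical nucleus", {
  spec <- class_spec("flat", intensity_noise_sd = 0, foci_mean = 0,
                     nucleus_radius_px = 20, nucleus_radius_sd = 0)
  rec <- synth_nucleus(spec, seed = 4)
  interior <- nucmorph:::gray_erode3(nucmorph:::gray_erode3(nucmorph:::gray_erode3(rec$mask))) > 0
  expect_true(all(rec$crop[interior] == spec$base_intensity))
  # outside the mask stays at background level
  outside <- !nucmorph:::gray_dilate3(nucmorph:::gray_dilate3(nucmorph:::gray_dilate3(rec$mask)))
  expect_lt(mean(rec$crop[outside]), 100)
})

test_that("generation is a pure function of spec and seed", {
  spec <- preset_classes()$condensed
  a <- synth_nucleus(spec, seed = 11)
  b <- synth_nucleus(spec, seed = 11)
  expect_identical(a$crop, b$crop)
  expect_identical(a$mask, b$mask)
  f1 <- synth_field(preset_classes(), 4, seed = 5)
  f2 <- synth_field(preset_classes(), 4, seed = 5)
  expect_identical(f1$field$pixels, f2$field$pixels)
  expect_identical(f1$labels, f2$labels)
})

test_that("all synthetic pixels stay within the 12-bit range", {
  for (s in 1:3) {
    fs <- synth_field(preset_classes(), 3, seed = s)
    expect_true(all(fs$field$pixels >= 0 & fs$field$pixels <= 4095))
    fd <- apply_corruption(fs, noise_spec(drift_vector = c(6, 2)))
    expect_true(all(fd$field$pixels >= 0 & fd$field$pixels <= 4095))
  }
})

test_that("focus centres lie inside the mask and oversized nuclei error", {
  rec <- synth_nucleus(preset_classes()$condensed, seed = 3)
  if (nrow(rec$foci)) {
    expect_true(all(rec$mask[rec$foci]))
  }
  big <- class_spec("big", nucleus_radius_px = 70, nucleus_radius_sd = 0)
  expect_error(synth_nucleus(big, seed = 1), class = "nm_parameter_error")
})

test_that("expected HC/EC increases with focus gain and count", {
  spec_hi <- class_spec("hi", foci_gain = 2.0, foci_mean = 30)
  spec_lo <- class_spec("lo", foci_gain = 1.2, foci_mean = 5)
  r_hi <- chromatin_table(synth_nuclei(spec_hi, 100, seed = 21))$ratio
  r_lo <- chromatin_table(synth_nuclei(spec_lo, 100, seed = 22))$ratio
  expect_gt(mean(r_hi), mean(r_lo))
  expect_lt(t.test(r_hi, r_lo)$p.value, 0.01)
})

test_that("synth_field places the requested nuclei disjointly or errors", {
  empty <- synth_field(preset_classes()$open, 0, seed = 1)
  expect_identical(max(empty$labels), 0L)
  expect_length(empty$masks, 0)

  fs <- synth_field(preset_classes(), 5, seed = 2)
  ids <- setdiff(unique(as.vector(fs$labels)), 0L)
  expect_length(ids, 5)
  # pairwise disjoint ground truth
  overlap <- Reduce(`+`, lapply(fs$masks, as.numeric))
  expect_true(all(overlap <= 1))

  expect_error(synth_field(preset_classes()$open, 25, seed = 3, width = 220L,
                           height = 220L),
               class = "nm_placement_error")
})

test_that("drift blur preserves the histogram but removes fine texture", {
  fs <- synth_field(preset_classes()$condensed, 4, seed = 8)
  same <- apply_corruption(fs, noise_spec(drift_vector = c(0, 0)))
  expect_identical(same$field$pixels, fs$field$pixels)

  blurred <- apply_corruption(fs, noise_spec(drift_vector = c(8, 0)))
  id <- 1L
  v0 <- fs$field$pixels[fs$labels == id]
  v1 <- blurred$field$pixels[fs$labels == id]
  q0 <- quantile(v0, c(0.25, 0.5, 0.75))
  q1 <- quantile(v1, c(0.25, 0.5, 0.75))
  expect_true(all(abs(q0 - q1) / (q0 + 1) < 0.15))

  # high-frequency band energy drops
  band_energy <- function(px) {
    f <- Mod(stats::fft(px - mean(px)))
    n <- nrow(px)
    hi <- c((n %/% 4):(3 * n %/% 4))
    sum(f[hi, hi]^2)
  }
  expect_lt(band_energy(blurred$field$pixels * 1.0),
            0.5 * band_energy(fs$field$pixels * 1.0))
})

test_that("overexposure corruption only raises pixel values", {
  fs <- synth_field(preset_classes()$open, 3, seed = 12)
  hot <- apply_corruption(fs, noise_spec(overexposure_fraction = 0.3),
                          nuclei = 2L)
  expect_true(all(hot$field$pixels >= fs$field$pixels))
  frac <- mean(hot$field$pixels[fs$labels == 2L] > 3700)
  expect_gte(frac, 0.3)
})
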