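make_flat_record <- function(canvas = 22L, value = 1000L) {
  nucmorph:::new_record(crop = matrix(value, canvas, canvas),
                        mask = matrix(TRUE, canvas, canvas), id = 1L)
}

test_that("the patch classifier is small, odd-sized and fully convolutional", {
  net <- build_patchnet(11L, 2L)
  types <- vapply(net$layers, `[[`, "", "type")
  expect_identical(sum(types == "conv"), 3L)
  # receptive field of three 3x3 convolutions is 7 px <= patch size
  expect_lte(1L + 3L * 2L, net$input_hw)
  expect_error(build_patchnet(12L, 2L), "odd")
})

test_that("image probability is the mean over retained patches", {
  rec <- make_flat_record(22L)
  net <- build_patchnet(11L, 2L, seed = 5)
  # 2x2 lattice of identical flat patches
  out <- suppressWarnings(predict_image(net, rec, stride = 11L))
  expect_identical(nrow(out$heatmap), 4L)
  px <- simplify2array(rep(list(rec$crop[1:11, 1:11]), 4))
  pp <- suppressWarnings(predict(net, px))
  expect_equal(unname(out$probs), unname(colMeans(pp)), tolerance = 1e-12)
  # identical patches: image probability equals the single-patch probability
  expect_equal(unname(out$probs), unname(pp[1, ]), tolerance = 1e-12)
  expect_equal(sum(out$probs), 1, tolerance = 1e-9)
})

test_that("a hand-built 4-patch fixture averages exactly", {
  rec <- make_flat_record(22L)
  # four distinct quadrants
  rec$crop[1:11, 1:11] <- 200L
  rec$crop[12:22, 1:11] <- 900L
  rec$crop[1:11, 12:22] <- 1600L
  rec$crop[12:22, 12:22] <- 2800L
  net <- build_patchnet(11L, 2L, seed = 9)
  out <- suppressWarnings(predict_image(net, rec, stride = 11L))
  quads <- simplify2array(list(rec$crop[1:11, 1:11], rec$crop[12:22, 1:11],
                               rec$crop[1:11, 12:22], rec$crop[12:22, 12:22]))
  manual <- colMeans(suppressWarnings(predict(net, quads)))
  expect_equal(unname(out$probs), unname(manual), tolerance = 1e-12)
})

test_that("image probability is invariant to patch enumeration order", {
  rec <- synth_nucleus(preset_classes()$condensed, seed = 12)
  net <- build_patchnet(11L, 2L, seed = 2)
  patches <- extract_patches(rec, size = 11L, stride = 4L)
  px <- simplify2array(lapply(patches, `[[`, "pixels"))
  pp <- suppressWarnings(predict(net, px))
  withr::local_seed(1)
  perm <- sample(nrow(pp))
  expect_equal(colMeans(pp), colMeans(pp[perm, , drop = FALSE]))
  out <- suppressWarnings(predict_image(net, rec, stride = 4L))
  expect_equal(unname(out$probs), unname(colMeans(pp)), tolerance = 1e-12)
})

test_that("zero retained patches is an error", {
  rec <- make_flat_record(22L)
  rec$mask[] <- FALSE
  net <- build_patchnet(11L, 2L)
  expect_error(suppressWarnings(predict_image(net, rec)),
               class = "nm_degenerate_input")
})

test_that("filter heat-maps align with the crop and localise bright foci", {
  rec <- synth_nucleus(preset_classes()$open, seed = 3)
  net <- build_patchnet(11L, 2L, seed = 1)
  expect_error(filter_heatmaps(net, rec), "trained")

  # deterministic weights: filter 1 becomes a 3x3 box blur passed through
  f <- net$n_filters
  net$layers[[2]]$W[1, ] <- 1 / 9
  passthrough <- function(C) { w <- rep(0, 9 * C); w[1 + C * 4] <- 1; w }
  net$layers[[4]]$W[1, ] <- passthrough(f)
  net$layers[[6]]$W[1, ] <- passthrough(f)
  for (i in c(3, 5, 7)) net$layers[[i]]$alpha <- 1  # linear activations
  net$trained <- TRUE

  maps <- filter_heatmaps(net, rec)
  expect_identical(dim(maps), c(128L, 128L, f))

  # constant input gives a spatially constant interior map
  flat <- make_flat_record(32L)
  mflat <- filter_heatmaps(net, flat)[5:28, 5:28, 1]
  expect_lt(diff(range(mflat)), 1e-9)

  # the blur filter peaks at the brightest chromatin focus
  m1 <- maps[, , 1]
  peak <- which(m1 == max(m1), arr.ind = TRUE)[1, ]
  bright <- which(rec$crop == max(rec$crop), arr.ind = TRUE)
  expect_lte(min(sqrt((bright[, 1] - peak[1])^2 + (bright[, 2] - peak[2])^2)), 4)
})
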