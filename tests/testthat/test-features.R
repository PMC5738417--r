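test_that("shape features match analytic oracles", {
  n <- 64; ctr <- 32.5
  disk <- sqrt(outer((1:n) - ctr, rep(1, n))^2 +
                 outer(rep(1, n), (1:n) - ctr)^2) <= 20
  sf <- shape_features(disk)
  expect_equal(sf[["shape_area"]], pi * 20^2, tolerance = 0.02)
  expect_lte(sf[["shape_eccentricity"]], 0.1)
  expect_gte(sf[["shape_roundness"]], 0.9)

  rect <- matrix(FALSE, 64, 64); rect[10:19, 10:49] <- TRUE
  sr <- shape_features(rect)
  expect_equal(sr[["shape_major_axis_length"]] /
                 sr[["shape_minor_axis_length"]], 4, tolerance = 0.02)
  expect_equal(sr[["shape_eccentricity"]], 0.97, tolerance = 0.01)

  one <- matrix(FALSE, 8, 8); one[4, 4] <- TRUE
  so <- shape_features(one)
  expect_equal(so[["shape_area"]], 1)
  expect_gte(so[["shape_minor_axis_length"]], 0)
  expect_error(shape_features(matrix(FALSE, 4, 4)),
               class = "nm_degenerate_input")
})

test_that("feature vectors have the documented dimensions", {
  rec <- fixture("feat_rec", synth_nucleus(preset_classes()$condensed, seed = 2))
  full <- morphometric_features(rec$crop, rec$mask, "nucleus")
  expect_length(full, 104)
  expect_identical(names(full), feature_names("nucleus"))
  patch <- extract_patches(rec)[[1]]
  pv <- morphometric_features(patch$pixels, NULL, "patch")
  expect_length(pv, 99)
  expect_identical(names(pv), feature_names("patch"))
  # the difference is exactly the 5-feature shape block
  expect_identical(setdiff(names(full), names(pv)),
                   nucmorph:::shape_feature_names)
  expect_true(all(is.finite(full)) && all(is.finite(pv)))
  # LBP block normalised to a unit histogram
  expect_equal(sum(full[grepl("^lbp_", names(full))]), 1)
})

test_that("features are deterministic and shape is intensity-invariant", {
  rec <- fixture("feat_rec", synth_nucleus(preset_classes()$condensed, seed = 2))
  a <- morphometric_features(rec$crop, rec$mask, "nucleus")
  b <- morphometric_features(rec$crop, rec$mask, "nucleus")
  expect_identical(a, b)
  expect_identical(shape_features(rec$mask),
                   a[nucmorph:::shape_feature_names])
})

test_that("texture features are invariant to integer mask translation", {
  rec <- fixture("feat_rec", synth_nucleus(preset_classes()$condensed, seed = 2))
  shift <- function(m, d) {
    out <- m * 0
    out[(1 + d):128, (1 + d):128] <- m[1:(128 - d), 1:(128 - d)]
    out
  }
  a <- texture_features(rec$crop, rec$mask)
  b <- texture_features(matrix(as.integer(shift(rec$crop, 7)), 128),
                        shift(rec$mask * 1, 7) > 0)
  expect_equal(a, b, tolerance = 1e-8)
})

test_that("rotation-describable blocks are invariant under 90-degree rotation", {
  rec <- fixture("feat_rec", synth_nucleus(preset_classes()$condensed, seed = 2))
  rot <- function(m) t(m)[ncol(m):1, ]
  a <- morphometric_features(rec$crop, rec$mask, "nucleus")
  b <- morphometric_features(rot(rec$crop), rot(rec$mask), "nucleus")
  lz <- grepl("^(lbp|zernike)_", names(a))
  expect_equal(a[lz], b[lz], tolerance = 1e-6)
})

test_that("a constant disk concentrates LBP mass in the flat pattern", {
  n <- 64; ctr <- 32.5
  disk <- sqrt(outer((1:n) - ctr, rep(1, n))^2 +
                 outer(rep(1, n), (1:n) - ctr)^2) <= 20
  img <- matrix(0L, n, n); img[disk] <- 1000L
  lb <- nucmorph:::lbp_features(img, disk)
  for (r in c(2, 3)) {
    block <- lb[grepl(sprintf("^lbp_r%d", r), names(lb))]
    expect_identical(names(which.max(block)), sprintf("lbp_r%d_b08", r))
  }
  expect_error(texture_features(matrix(1, 3, 3), matrix(TRUE, 3, 3)),
               class = "nm_degenerate_input")
})

test_that("texture separates the two synthetic classes", {
  sets <- fixture("two_class_small", two_class_nuclei(30L, seed = 71))
  fo <- feature_matrix(assemble_features(sets$open))
  fc <- feature_matrix(assemble_features(sets$condensed))
  tex <- grepl("^(lbp|pftas|zernike)_", colnames(fo))
  p_min <- min(vapply(which(tex), function(j) {
    if (sd(fo[, j]) + sd(fc[, j]) == 0) return(1)
    t.test(fo[, j], fc[, j])$p.value
  }, 0))
  expect_lt(p_min, 0.01)
})

test_that("assembly validates input kinds and headers", {
  sets <- fixture("two_class_small", two_class_nuclei(30L, seed = 71))
  tbl <- assemble_features(sets$open[1:3])
  expect_identical(dim(feature_matrix(tbl)), c(3L, 104L))
  patches <- extract_patches(sets$open[[1]])
  ptbl <- assemble_features(patches)
  expect_identical(dim(feature_matrix(ptbl)),
                   c(length(patches), 99L))
  empty <- assemble_features(list())
  expect_identical(nrow(empty), 0L)
  expect_true(all(feature_names("nucleus") %in% names(empty)))
  expect_error(assemble_features(c(sets$open[1], patches[1])), "mixed")
})
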