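test_that("watershed splits two overlapping discs and keeps one disc whole", {
  n <- 64
  # centers 1.5 radii apart: overlapping but two cores
  m <- disc_mask(n, rbind(c(26, 32), c(41, 32)), c(10, 10))
  lab <- watershed_segment(binary_image(m, 1))
  expect_equal(max(lab), 2)

  one <- disc_mask(n, rbind(c(32, 32)), 12)
  lab1 <- watershed_segment(binary_image(one, 1))
  expect_equal(max(lab1), 1)
  expect_equal(sum(lab1 > 0), sum(one))
})

test_that("watershed labels partition the foreground", {
  pk <- granule_packing(c(A = 1, B = 5, C = 12), 256, 0.5, seed = 4)
  lab <- watershed_segment(pk$image)
  expect_equal(sum(lab > 0), sum(pk$image$mask))
  expect_true(all(lab[pk$image$mask] > 0))
  expect_true(all(lab[!pk$image$mask] == 0))
})

test_that("empty mask yields an empty labeling with a warning", {
  expect_warning(
    lab <- watershed_segment(binary_image(matrix(FALSE, 8, 8))),
    "empty")
  expect_equal(max(lab), 0)
  expect_equal(nrow(measure_granules(lab, 0.5)), 0)
})

test_that("granule areas follow pixel count times squared scale", {
  lab <- matrix(0L, 20, 20)
  lab[3:12, 3:12] <- 1L  # 100 px
  gs <- measure_granules(lab, 0.5)
  expect_equal(gs$area_um2, 25)
  expect_equal(gs$equiv_diameter_um, 2 * sqrt(25 / pi))
  expect_equal(attr(gs, "image_area_um2"), 400 * 0.25)
  expect_error(measure_granules(lab, 0), "positive")
})

test_that("measured granule areas match the analytic disc ground truth", {
  pk <- granule_packing(c(A = 2, B = 6, C = 10), 384, 0.5, seed = 6)
  lab <- watershed_segment(pk$image)
  gs <- measure_granules(lab, 0.5)
  expect_equal(nrow(gs), nrow(pk$granules))
  # match by nearest centroid
  want <- pk$granules
  idx <- vapply(seq_len(nrow(want)), function(i) {
    which.min((gs$centroid_row - want$x_px[i])^2 +
              (gs$centroid_col - want$y_px[i])^2)
  }, integer(1))
  rel_err <- abs(gs$area_um2[idx] - want$area_um2) / want$area_um2
  expect_lt(max(rel_err), 0.15)   # discretization of the smallest discs
  big <- want$area_um2 > 50
  expect_lt(max(rel_err[big]), 0.03)
})

test_that("granule classification applies the 20/177 um^2 bands", {
  expect_equal(as.character(classify_granules(c(510.429, 100, 10))),
               c("A", "B", "C"))
  # circle area at exactly 15 um diameter sits below the rounded 177 cutoff
  expect_equal(as.character(classify_granules(pi * 7.5^2)), "B")
  expect_equal(as.character(classify_granules(c(20, 177))), c("B", "B"))
  cuts <- granule_area_cutoffs()
  expect_equal(unname(cuts), c(177, 20))
  expect_equal(unname(granule_area_cutoffs(round_to_integer = FALSE)),
               c(pi * 7.5^2, pi * 2.5^2))
})

test_that("type percentages sum to 100", {
  pk <- granule_packing(c(A = 1, B = 4, C = 9), 256, 0.5, seed = 8)
  gs <- classify_granules(measure_granules(watershed_segment(pk$image), 0.5))
  ts <- attr(gs, "type_summary")
  expect_equal(sum(ts$percent), 100, tolerance = 1e-9)
  expect_equal(ts$count, c(1L, 4L, 9L))
})

test_that("minkowski functionals match hand-derived small cases", {
  m <- matrix(FALSE, 2, 2); m[1, 1] <- TRUE
  mk <- minkowski_functionals(binary_image(m))
  expect_equal(mk$V, 25)
  expect_equal(mk$N_bound, 2L)
  expect_equal(mk$S, 50)
  expect_equal(mk$chi, 0)

  allw <- minkowski_functionals(binary_image(matrix(TRUE, 5, 5)))
  expect_equal(allw$V, 100)
  expect_equal(allw$S, 0)
  expect_equal(allw$chi, 1 / 25)

  # checkerboard: pathological input where S exceeds 100%
  cb <- outer(1:4, 1:4, "+") %% 2 == 0
  mkc <- minkowski_functionals(binary_image(cb))
  expect_equal(mkc$N_bound, 24L)
  expect_equal(mkc$S, 150)
  expect_equal(mkc$C_w, 1L)  # diagonal-connected whites
  expect_equal(mkc$C_b, 8L)  # isolated blacks
})

test_that("minkowski functionals equal the brute-force oracle on random images", {
  set.seed(101)
  for (i in 1:25) {
    nr <- sample(3:24, 1); nc <- sample(3:24, 1)
    m <- random_mask(nr, nc, runif(1, 0.2, 0.8))
    mk <- minkowski_functionals(binary_image(m))
    or <- oracle_minkowski(m)
    expect_identical(mk$N_bound, or$N_bound)
    expect_identical(mk$C_w, or$C_w)
    expect_identical(mk$C_b, or$C_b)
    expect_equal(mk$V, or$V)
    expect_equal(mk$S, or$S)
    expect_equal(mk$chi, or$chi)
  }
})

test_that("euler characteristic is invariant to translation and rotation", {
  set.seed(7)
  m <- disc_mask(32, rbind(c(10, 10), c(24, 20)), c(4, 6))
  chi0 <- minkowski_functionals(binary_image(m))$chi
  shifted <- matrix(FALSE, 32, 32)
  shifted[4:32, 2:32] <- m[1:29, 1:31]
  expect_equal(minkowski_functionals(binary_image(shifted))$chi, chi0)
  rot <- t(m)[, rev(seq_len(32))]  # 90 degree rotation
  expect_equal(minkowski_functionals(binary_image(rot))$chi, chi0)
})

test_that("k disjoint discs give C_w = k, C_b = 1, chi = (k-1)/N", {
  pk <- granule_packing(c(A = 0, B = 3, C = 4), 192, 0.5, seed = 9)
  mk <- minkowski_functionals(pk$image)
  expect_equal(mk$C_w, 7L)
  expect_equal(mk$C_b, 1L)
  expect_equal(mk$chi, (7 - 1) / (192 * 192))
  expect_equal(mk$V + mk$void_share, 100)
})

test_that("coverage rate is count over area", {
  expect_equal(coverage_rate(50, image_area_um2 = 1000), 0.05)
  pk <- granule_packing(c(A = 0, B = 2, C = 6), 192, 0.5, seed = 10)
  em <- endosperm_morphology(pk$image)
  expect_equal(em$coverage_rate_um2, 8 / (192 * 192 * 0.25))
  lab <- matrix(0L, 4, 4)
  expect_equal(coverage_rate(measure_granules(lab, 1)), 0)
  expect_error(coverage_rate(5, image_area_um2 = 0), "positive")
})
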