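test_that("Otsu threshold: two-level image and degenerate input", {
  x <- c(rep(0, 5), rep(10, 5))
  expect_equal(otsu_threshold(x), 0)
  # between-class variance at t=0 is 0.25 * 10^2 = 25, the maximum
  expect_error(otsu_threshold(c(5, 5, 5)), "degenerate histogram")
  # histogram-form input
  expect_identical(otsu_threshold(list(levels = c(0, 10), counts = c(5, 5))),
                   0)
})

test_that("Otsu threshold equals the exhaustive scan on random histograms", {
  set.seed(71)
  for (i in 1:50) {
    x <- sample(0:7, 150, replace = TRUE,
                prob = runif(8))
    if (length(unique(x)) < 2) next
    expect_equal(otsu_threshold(x), as.numeric(otsu_bruteforce(x)))
  }
  # continuous intensities too
  for (i in 1:10) {
    x <- round(c(rnorm(80, 10, 2), rnorm(20, 30, 4)), 1)
    expect_equal(otsu_threshold(x), as.numeric(otsu_bruteforce(x)))
  }
})

test_that("connected-component labeling agrees with flood fill on toys", {
  set.seed(72)
  for (i in 1:25) {
    m <- matrix(runif(64) < 0.4, 8, 8)
    got <- granulekit:::.label_components8(m)
    want <- label_bruteforce(m)
    # same partition: labels may differ, component memberships must not
    expect_identical(max(got), max(want))
    expect_true(all(tapply(want[m], got[m],
                           function(v) length(unique(v))) == 1))
  }
})

test_that("all-background image yields zero granules", {
  fi <- field_image(list(A = matrix(7, 40, 40)), pixel_size = 0.1,
                    cell_mask = {
                      m <- matrix(0L, 40, 40); m[5:35, 5:35] <- 1L; m
                    })
  expect_warning(gs <- segment_granules(fi, "A"), "degenerate")
  expect_identical(nrow(gs), 0L)
  fi_empty <- field_image(list(A = matrix(7, 40, 40)), pixel_size = 0.1,
                          cell_mask = matrix(0L, 40, 40))
  expect_error(segment_granules(fi_empty, "A"), "empty cell mask")
})

test_that("size gate at 0.1 um/px: 0.3 and 2.5 um rejected, 1.0 um kept", {
  img <- matrix(10, 100, 100)
  img <- draw_disk(img, 25, 25, 0.3, 0.1, 200)   # too small
  img <- draw_disk(img, 25, 70, 1.0, 0.1, 200)   # in gate
  img <- draw_disk(img, 70, 45, 2.5, 0.1, 200)   # too large
  mask <- matrix(1L, 100, 100)
  fi <- field_image(list(A = img), pixel_size = 0.1, cell_mask = mask)
  gs <- segment_granules(fi, "A", gate = c(0.4, 2.0))
  expect_identical(nrow(gs), 1L)
  expect_equal(gs$row_px, 25, tolerance = 0.5)
  expect_equal(gs$col_px, 70, tolerance = 0.5)
  expect_true(gs$eq_diam_um >= 0.4 && gs$eq_diam_um <= 2.0)
})

test_that("border-touching and cell-spanning components are discarded", {
  img <- matrix(0, 60, 60)
  img <- draw_disk(img, 3, 30, 1.0, 0.1, 200)    # touches top border
  img <- draw_disk(img, 30, 30, 1.0, 0.1, 200)   # straddles two cells
  img <- draw_disk(img, 45, 15, 1.0, 0.1, 200)   # clean, inside cell 1
  mask <- matrix(1L, 60, 60); mask[, 31:60] <- 2L
  fi <- field_image(list(A = img), pixel_size = 0.1, cell_mask = mask)
  gs <- segment_granules(fi, "A")
  expect_identical(nrow(gs), 1L)
  expect_identical(gs$cell_id, 1L)
})

test_that("gate monotonicity and intensity-scale invariance", {
  sf <- synth_field_image(n_cells = 3, granules_per_cell = 6,
                          diameter_range = c(0.6, 1.6), seed = 73)
  fi <- correct_image(sf$image)
  counts <- vapply(c(0.4, 0.8, 1.0, 1.2), function(gmin)
    nrow(segment_granules(fi, "A", gate = c(gmin, 2.0))), integer(1))
  expect_true(all(diff(counts) <= 0))
  # multiplying the image by a positive constant leaves segmentation
  # pixel-identical
  gs1 <- segment_granules(fi, "A")
  fi2 <- fi; fi2$channels$A <- fi$channels$A * 4
  gs2 <- segment_granules(fi2, "A")
  expect_identical(attr(gs1, "pixel_sets"), attr(gs2, "pixel_sets"))
  expect_equal(gs1$row_px, gs2$row_px)
  # every returned diameter respects the gate
  expect_true(all(gs1$eq_diam_um >= 0.4 & gs1$eq_diam_um <= 2.0))
})

test_that("per-cell thresholding works and records per-cell thresholds", {
  sf <- synth_field_image(n_cells = 3, granules_per_cell = 6,
                          diameter_range = c(0.6, 1.6), seed = 74)
  fi <- correct_image(sf$image)
  gs <- segment_granules(fi, "A", per_cell = TRUE)
  expect_identical(length(attr(gs, "threshold")), 3L)
  expect_gt(nrow(gs), 0L)
})

test_that("detection recovers planted granules on the seed-1 field", {
  # regression against the generator's ground truth (SNR ~ 10)
  sf <- synth_field_image(diameter_range = c(0.6, 1.6), seed = 1)
  fi <- correct_image(sf$image)
  gs <- segment_granules(fi, "A")
  sc <- score_detection(sf$truth$granules, gs)
  expect_gte(sc$recall, 0.95)
  expect_gte(sc$precision, 0.95)
})
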