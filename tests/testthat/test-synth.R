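test_that("field generator is bit-for-bit reproducible under a seed", {
  a <- synth_field_image(n_cells = 2, granules_per_cell = 4, seed = 11)
  b <- synth_field_image(n_cells = 2, granules_per_cell = 4, seed = 11)
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth$granules, b$truth$granules)
  c <- synth_field_image(n_cells = 2, granules_per_cell = 4, seed = 12)
  expect_false(identical(a$image$channels$A, c$image$channels$A))
})

test_that("planted granules respect their cell masks and diameter range", {
  sf <- synth_field_image(n_cells = 3, granules_per_cell = 8,
                          diameter_range = c(0.6, 1.6), seed = 21)
  g <- sf$truth$granules
  mask <- sf$truth$cell_mask
  at_centroid <- mask[cbind(round(g$row_px), round(g$col_px))]
  expect_equal(at_centroid, g$cell_id)
  expect_true(all(g$diameter_um >= 0.6 & g$diameter_um <= 1.6))
})

test_that("zero granules per cell gives baseline-only cells", {
  sf <- synth_field_image(n_cells = 2, granules_per_cell = 0,
                          illum_magnitude = 0, autofluorescence = 0,
                          noise = FALSE, baseline_A = 50, seed = 5)
  expect_identical(nrow(sf$truth$granules), 0L)
  inside <- sf$image$channels$A[sf$truth$cell_mask > 0]
  outside <- sf$image$channels$A[sf$truth$cell_mask == 0]
  expect_true(all(inside == 50))
  expect_true(all(outside == 0))
})

test_that("planting outside the detection gate warns but proceeds", {
  expect_warning(
    sf <- synth_field_image(n_cells = 1, granules_per_cell = 2,
                            diameter_range = c(2.2, 2.6), seed = 31),
    "outside the detection gate")
  expect_true(all(sf$truth$granules$diameter_um >= 2.2))
  expect_error(synth_field_image(width = -4, seed = 1), "dimensions")
  expect_error(synth_field_image(pixel_size = 0, seed = 1), "pixel_size")
})

test_that("planted enrichment is exact on the noiseless flat-field image", {
  # the cross-module consistency invariant: fold computed by the
  # enrichment engine on planted pixel sets equals the planted fold
  sf <- synth_field_image(illum_magnitude = 0, autofluorescence = 0,
                          noise = FALSE, enrichment_fold = 3, seed = 1)
  ts <- truth_granule_set(sf, which = "recruiting")
  fe <- fold_enrichment(ts, sf$image$channels$B, sf$truth$cell_mask)
  expect_lt(max(abs(fe$per_granule$fold - 3)) / 3, 0.05)
  # non-recruiting granules carry no channel-B amplitude
  expect_true(all(sf$truth$granules$amplitude_B[!sf$truth$granules$recruiting]
                  == 0))
})

test_that("FRAP simulator matches its closed form at zero noise", {
  M <- 0.37; k <- 0.08; bd <- 0.25
  tr <- synth_frap_trace(M = M, k = k, bleach_depth = bd, dt = 2,
                         noise_sd = 0, n_pre = 4, n_post = 30, seed = 3)
  tau <- tr$times[tr$bleach_index:length(tr$times)] -
    tr$times[tr$bleach_index]
  expected <- bd + (1 - bd) * M * (1 - exp(-k * tau))
  expect_equal(tr$intensities[tr$bleach_index:length(tr$times)], expected,
               tolerance = 1e-12)
  expect_true(all(tr$intensities[1:3] == 1))
})

test_that("FRAP simulator limit cases behave", {
  # immobile: flat at bleach depth up to noise
  tr0 <- synth_frap_trace(M = 0, k = 0.05, bleach_depth = 0.2,
                          noise_sd = 0, seed = 1)
  post <- tr0$intensities[tr0$bleach_index:length(tr0$times)]
  expect_true(all(abs(post - 0.2) < 1e-12))
  # fully mobile and fast: immediately back near 1 after the first frame
  tr1 <- synth_frap_trace(M = 1, k = 100, bleach_depth = 0.2,
                          noise_sd = 0, seed = 1)
  post1 <- tr1$intensities[(tr1$bleach_index + 1):length(tr1$times)]
  expect_true(all(post1 > 0.999))
  expect_error(synth_frap_trace(M = 1.4, k = 1, seed = 1), "M")
  expect_error(synth_frap_trace(M = 0.5, k = 1, bleach_depth = 1, seed = 1),
               "bleach_depth")
})

test_that("densitometry generator: noiseless recovery and edge cases", {
  tab0 <- synth_densitometry(true_pellet_fraction = 0.65, lognormal_sd = 0,
                             n_replicates = 3, seed = 9)
  pf <- pellet_fraction_from_table(tab0)
  expect_equal(pf$per_replicate$fraction_pellet, rep(0.65, 3))
  tabz <- synth_densitometry(true_pellet_fraction = 0, lognormal_sd = 0.2,
                             n_replicates = 4, seed = 9)
  expect_true(all(tabz$band_intensity[tabz$condition == "pellet"] == 0))
})

test_that("densitometry generator: mean recovery under lognormal noise", {
  # law of large numbers on the stated noise model
  tab <- synth_densitometry(true_pellet_fraction = 0.8, lognormal_sd = 0.1,
                            n_replicates = 100, seed = 13)
  pf <- pellet_fraction_from_table(tab)
  expect_lt(abs(pf$mean - 0.8), 0.02)
})
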