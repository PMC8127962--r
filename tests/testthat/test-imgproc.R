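test_that("constant image yields a unit illumination field", {
  f <- estimate_illumination_field(matrix(100, 40, 40))
  expect_equal(as.vector(f), rep(1, 1600), tolerance = 1e-8)
})

test_that("a planted order-2 field is recovered within 2% RMS", {
  set.seed(101)
  h <- 120; w <- 120
  u <- matrix(seq(-1, 1, length.out = w), h, w, byrow = TRUE)
  v <- matrix(seq(-1, 1, length.out = h), h, w)
  p <- 0.12 * u + 0.08 * v - 0.1 * u * v + 0.06 * u^2 - 0.09 * v^2
  field <- exp(p); field <- field / mean(field)   # ~20% peak amplitude
  img <- 200 * field
  est <- estimate_illumination_field(img, poly_order = 2)
  expect_lt(sqrt(mean((est - field)^2)) / mean(field), 0.02)
})

test_that("the fit is robust to 5% bright outliers", {
  set.seed(102)
  h <- 120; w <- 120
  u <- matrix(seq(-1, 1, length.out = w), h, w, byrow = TRUE)
  v <- matrix(seq(-1, 1, length.out = h), h, w)
  field <- exp(0.15 * u - 0.1 * v^2 + 0.05 * u * v)
  field <- field / mean(field)
  img <- 200 * field
  n_out <- round(0.05 * length(img))
  img[sample(length(img), n_out)] <- img[sample(length(img), n_out)] * 10
  est <- estimate_illumination_field(img, poly_order = 2)
  expect_lt(sqrt(mean((est - field)^2)) / mean(field), 0.05)
})

test_that("degenerate fits are rejected with a helpful error", {
  expect_error(estimate_illumination_field(matrix(10, 2, 2), poly_order = 3),
               "order 3")
  # rank-deficient: usable pixels confined to one column
  img <- matrix(0, 30, 30); img[, 15] <- 50
  expect_error(estimate_illumination_field(img, poly_order = 2), "rank")
})

test_that("correct_image identities hold", {
  fi <- field_image(list(A = matrix(80, 20, 20)), pixel_size = 0.1,
                    cell_mask = matrix(1L, 20, 20))
  out <- correct_image(fi, illumination = matrix(1, 20, 20),
                       autofluorescence = 0)
  expect_equal(out$channels$A, fi$channels$A)
  # dividing a scaled flat field recovers a flat image
  fld <- matrix(exp(seq(-0.2, 0.2, length.out = 20)), 20, 20)
  fld <- fld / mean(fld)
  fi2 <- field_image(list(A = 80 * fld), pixel_size = 0.1,
                     cell_mask = matrix(1L, 20, 20))
  out2 <- correct_image(fi2, illumination = fld)
  expect_equal(max(out2$channels$A) - min(out2$channels$A), 0,
               tolerance = 1e-9)
  # nonnegativity after aggressive background subtraction
  out3 <- correct_image(fi, illumination = matrix(1, 20, 20),
                        autofluorescence = 100)
  expect_true(all(out3$channels$A >= 0))
  expect_error(correct_image(fi, illumination = matrix(0, 20, 20)),
               "strictly positive")
  expect_error(correct_image(fi, illumination = list(B = matrix(1, 20, 20))),
               "channel")
})

test_that("correction is idempotent on generator output", {
  sf <- synth_field_image(n_cells = 3, granules_per_cell = 5,
                          illum_magnitude = 0.2, noise = FALSE,
                          autofluorescence = 0, seed = 41)
  fi <- correct_image(sf$image, poly_order = 2)
  refit <- estimate_illumination_field(fi$channels$A,
                                       mask = fi$cell_mask > 0)
  expect_lt(max(abs(refit[fi$cell_mask > 0] - 1)), 0.05)
})

test_that("correction halves the cytosolic CV of the noiseless image", {
  sf <- synth_field_image(n_cells = 3, granules_per_cell = 5,
                          illum_magnitude = 0.2, autofluorescence = 20,
                          noise = FALSE, seed = 42)
  mask <- sf$truth$cell_mask
  g <- sf$truth$granules
  gran_pix <- unique(unlist(lapply(seq_len(nrow(g)), function(i)
    granulekit:::granule_disk_idx(g$row_px[i], g$col_px[i],
                                  3 * g$sigma_px[i], nrow(mask),
                                  ncol(mask)))))
  cyto <- setdiff(which(mask > 0), gran_pix)
  cv <- function(x) stats::sd(x) / mean(x)
  fi <- correct_image(sf$image, autofluorescence = 20)
  expect_lt(cv(fi$channels$A[cyto]), 0.5 * cv(sf$image$channels$A[cyto]))
})

test_that("fold enrichment needs the correction to be unbiased", {
  # planted 20%-amplitude field + autofluorescence bias the raw
  # estimate by >5%; correction restores it to within 5%
  sf <- synth_field_image(enrichment_fold = 3, illum_magnitude = 0.2,
                          autofluorescence = 20, seed = 43)
  ts <- truth_granule_set(sf, which = "recruiting")
  raw <- fold_enrichment(ts, sf$image$channels$B, sf$truth$cell_mask)
  fi <- correct_image(sf$image, autofluorescence = 20)
  cor <- fold_enrichment(ts, fi$channels$B, sf$truth$cell_mask)
  expect_gt(abs(raw$summary$mean - 3) / 3, 0.05)
  expect_lt(abs(cor$summary$mean - 3) / 3, 0.05)
})

test_that("autofluorescence estimator reads the background of control cells", {
  set.seed(44)
  img <- matrix(30, 50, 50) + rnorm(2500, 0, 0.5)
  mask <- matrix(0L, 50, 50); mask[10:40, 10:40] <- 1L
  expect_equal(estimate_autofluorescence(img, mask), 30, tolerance = 0.2)
  expect_error(estimate_autofluorescence(img, matrix(0L, 50, 50)), "empty")
})
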