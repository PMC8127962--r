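test_that("identical centroid lists match perfectly at distance zero", {
  A <- make_gset(c(10, 20, 30), c(10, 20, 30))
  B <- make_gset(c(10, 20, 30), c(10, 20, 30), channel = "B")
  r <- match_granules(A, B, cutoff = 0.5)
  expect_identical(nrow(r$matches), 3L)
  expect_true(all(r$matches$distance_um == 0))
  expect_equal(r$per_cell$fraction, 1)
  # empty B: zero matches, fraction 0
  B0 <- make_gset(numeric(0), numeric(0), channel = "B")
  r0 <- match_granules(A, B0, cutoff = 0.5)
  expect_identical(nrow(r0$matches), 0L)
  expect_equal(r0$per_cell$fraction, 0)
  expect_error(match_granules(A, make_gset(1, 1, image_id = "other")),
               "different images")
})

test_that("greedy matching equals exhaustive optimal matching on 5x5 sets", {
  # planted instances: each B granule sits near its own A granule
  # (3 within the cutoff, 2 displaced beyond it), A centroids well
  # separated -- the geometry of real two-channel granule scenes
  for (s in 1:20) {
    set.seed(s)
    ra <- runif(5, 10, 90); ca <- runif(5, 10, 90)
    while (min(dist(cbind(ra, ca))) < 15) {
      ra <- runif(5, 10, 90); ca <- runif(5, 10, 90)
    }
    off_small <- matrix(rnorm(6, 0, 1), 3, 2)          # < cutoff (px)
    off_big <- matrix(12 + runif(4, 0, 6), 2, 2)       # beyond cutoff
    rb <- ra + c(off_small[, 1], off_big[, 1])
    cb <- ca + c(off_small[, 2], off_big[, 2])
    A <- make_gset(ra, ca)
    B <- make_gset(rb, cb, channel = "B")
    r <- match_granules(A, B, cutoff = 0.5)            # 5 px at 0.1 um/px
    d <- sqrt(outer(ra, rb, `-`)^2 + outer(ca, cb, `-`)^2) * 0.1
    oracle <- match_bruteforce(d, 0.5)
    expect_identical(nrow(r$matches), oracle$count)
    got_pairs <- sort(paste(r$matches$A_id, r$matches$B_id))
    want_pairs <- sort(vapply(oracle$pairs, function(p)
      paste(p[1], p[2]), character(1)))
    expect_identical(got_pairs, want_pairs)
  }
})

test_that("matching is symmetric and monotone in the cutoff", {
  set.seed(81)
  A <- make_gset(runif(6, 5, 95), runif(6, 5, 95))
  B <- make_gset(runif(6, 5, 95), runif(6, 5, 95), channel = "B")
  for (cut in c(0.3, 0.6, 1.2)) {
    rab <- match_granules(A, B, cutoff = cut)
    rba <- match_granules(B, A, cutoff = cut)
    expect_identical(nrow(rab$matches), nrow(rba$matches))
    expect_equal(sort(rab$matches$distance_um), sort(rba$matches$distance_um))
  }
  counts <- vapply(c(0.2, 0.5, 1, 2, 5), function(cut)
    nrow(match_granules(A, B, cutoff = cut)$matches), integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("colocalization percentages are computed over the reference set", {
  A <- make_gset(c(10, 20, 30, 40), c(10, 20, 30, 40))
  B <- make_gset(c(10, 20, 30), c(10, 20, 30), channel = "B")
  r <- match_granules(A, B, cutoff = 0.5)
  cf <- colocalization_fraction(r, reference = "A")
  expect_equal(cf$pooled, 75)  # 3 matched of 4 reference granules
  cfB <- colocalization_fraction(r, reference = "B")
  expect_equal(cfB$pooled, 100)
})

test_that("fold enrichment: uniform channel, direct ratio, invariances", {
  sf <- synth_field_image(n_cells = 2, granules_per_cell = 4,
                          illum_magnitude = 0, autofluorescence = 0,
                          noise = FALSE, seed = 82)
  ts <- truth_granule_set(sf)
  mask <- sf$truth$cell_mask
  # spatially uniform signal: fold exactly 1 for every granule
  uni <- matrix(0, nrow(mask), ncol(mask)); uni[mask > 0] <- 123
  fe1 <- fold_enrichment(ts, uni, mask)
  expect_equal(fe1$per_granule$fold, rep(1, nrow(ts)))
  # direct ratio: granule pixels at 300 over a 100-mean cell
  fe3 <- fold_enrichment(ts, sf$image$channels$B, mask)
  fe3s <- fold_enrichment(ts, sf$image$channels$B * 7.3, mask)
  expect_equal(fe3$per_granule$fold, fe3s$per_granule$fold)  # scale-free
  expect_error(fold_enrichment(ts, uni * 0, mask), "zero whole-cell mean")
})

test_that("hand-built ratio: granule mean 300 over cell mean 100 gives 3", {
  img <- matrix(0, 30, 30)
  mask <- matrix(0L, 30, 30); mask[2:29, 2:29] <- 1L
  n_cell <- sum(mask)
  # granule: 9 pixels at value g, rest at value b with cell mean 100
  gpix <- as.vector(outer(10:12, (9:11) * 30, `+`))
  b <- (100 * n_cell - 9 * 300) / (n_cell - 9)
  img[mask > 0] <- b
  img[gpix] <- 300
  gs <- make_gset(11, 10)
  attr(gs, "pixel_sets") <- list(gpix)
  attr(gs, "dim_px") <- c(30L, 30L)
  fe <- fold_enrichment(gs, img, mask)
  expect_equal(fe$per_granule$fold, 3, tolerance = 1e-12)
})

test_that("non-recruiting granules trend to fold 1 as noise vanishes", {
  # in a recruitment-free scene channel B is uniform inside cells, so
  # every granule must read fold 1 exactly on the noiseless image
  sf <- synth_field_image(recruit_fraction = 0, noise = FALSE,
                          illum_magnitude = 0, autofluorescence = 0,
                          seed = 83)
  ts <- truth_granule_set(sf)
  fe <- fold_enrichment(ts, sf$image$channels$B, sf$truth$cell_mask)
  expect_lt(max(abs(fe$per_granule$fold - 1)), 1e-9)
  # with mild noise the mean stays near 1
  sfn <- synth_field_image(recruit_fraction = 0, illum_magnitude = 0,
                           autofluorescence = 0, seed = 83)
  fen <- fold_enrichment(truth_granule_set(sfn), sfn$image$channels$B,
                         sfn$truth$cell_mask)
  expect_lt(abs(fen$summary$mean - 1), 0.05)
})
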