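#' Generate a synthetic granule field image with ground truth
#'
#' Renders a multi-cell, two-channel fluorescence field emulating
#' cytoplasmic protein granules: non-overlapping elliptical cells on a
#' dark background, bright sub-resolution-to-2-um granules rendered as
#' 2D Gaussians (sigma = diameter / 2.355, the FWHM convention), a
#' second channel whose recruiting granules carry a planted
#' fold-enrichment, a smooth multiplicative illumination field
#' (exponentiated low-order 2D polynomial), additive autofluorescence,
#' and Poisson shot noise on a photon-scaled signal followed by additive
#' Gaussian read noise.
#'
#' Channel B amplitudes are solved per cell so that, on the noiseless
#' flat-illumination image, the within-cell fold enrichment of each
#' recruiting granule (mean channel-B intensity over the granule's
#' half-maximum disk divided by the whole-cell mean) equals
#' `enrichment_fold` exactly up to pixel discretization.
#'
#' @param width,height image size in pixels.
#' @param pixel_size micrometres per pixel (default 0.1).
#' @param n_cells number of cells to place.
#' @param granules_per_cell integer count, or a function of one argument
#'   (the number of cells) returning integer counts.
#' @param diameter_range granule diameter range in micrometres; the
#'   default 0.4--2 um spans the detection size gate.
#' @param baseline_A,amplitude_A cytosolic baseline and granule peak
#'   amplitude of the granule channel (a.u.).
#' @param baseline_B cytosolic baseline of the signaling channel (a.u.).
#' @param recruit_fraction probability that a granule recruits channel-B
#'   signal.
#' @param enrichment_fold planted fold enrichment of recruiting granules
#'   (>= 1).
#' @param illum_order,illum_magnitude polynomial order and peak relative
#'   amplitude of the multiplicative illumination field; magnitude 0
#'   gives a flat field.
#' @param autofluorescence additive background level (a.u.).
#' @param photon_scale photons per intensity unit for the Poisson stage.
#' @param read_noise_sd Gaussian read-noise standard deviation (a.u.).
#' @param noise logical; `FALSE` returns the noiseless image.
#' @param detection_gate diameter gate used downstream; planting outside
#'   it only warns (needed for gate tests).
#' @param cell_axis_range semi-axis range of the elliptical cells, px.
#' @param seed integer seed; required, for exact reproducibility.
#' @return a list with elements `image` (a [field_image()] with channels
#'   `A` and `B`) and `truth` (ground truth: `granules` data frame with
#'   cell_id, row_px, col_px, diameter_um, recruiting, amplitude_A,
#'   amplitude_B; `planted_enrichment`; `illumination_coeffs`;
#'   `illumination` field matrix; `cell_mask`; `noiseless` channel list;
#'   `seed`).
#' @examples
#' sf <- synth_field_image(n_cells = 2, granules_per_cell = 3, seed = 1)
#' nrow(sf$truth$granules)
#' @export
synth_field_image <- function(width = 512, height = 512, pixel_size = 0.1,
                              n_cells = 5, granules_per_cell = 10,
                              diameter_range = c(0.4, 2.0),
                              baseline_A = 50, amplitude_A = 200,
                              baseline_B = 100,
                              recruit_fraction = 1, enrichment_fold = 3,
                              illum_order = 2, illum_magnitude = 0.2,
                              autofluorescence = 20,
                              photon_scale = 1, read_noise_sd = 2,
                              noise = TRUE,
                              detection_gate = c(0.4, 2.0),
                              cell_axis_range = c(60, 80),
                              seed) {
  if (missing(seed)) gk_stop("`seed` is required for reproducibility")
  gk_check_positive(pixel_size, "pixel_size")
  if (width < 16 || height < 16) gk_stop("image dimensions must be >= 16 px")
  if (length(diameter_range) != 2L || any(diameter_range <= 0) ||
      diameter_range[1] > diameter_range[2])
    gk_stop("`diameter_range` must be an increasing positive pair (um)")
  if (diameter_range[1] < 2 * pixel_size)
    gk_stop("minimum diameter below image resolution (2 px)")
  gk_check_fraction(recruit_fraction, "recruit_fraction")
  if (enrichment_fold < 1) gk_stop("`enrichment_fold` must be >= 1")
  if (diameter_range[1] < detection_gate[1] ||
      diameter_range[2] > detection_gate[2])
    warning("planted diameter range extends outside the detection gate",
            call. = FALSE)
  set.seed(as.integer(seed))

  mask <- matrix(0L, height, width)
  cells <- place_cells(width, height, n_cells, cell_axis_range)
  for (i in seq_len(n_cells)) {
    cl <- cells[[i]]
    mask[ellipse_pixels(height, width, cl)] <- i
  }

  counts <- if (is.function(granules_per_cell)) {
    as.integer(granules_per_cell(n_cells))
  } else rep(as.integer(granules_per_cell), n_cells)
  if (length(counts) != n_cells || any(counts < 0))
    gk_stop("granules_per_cell must yield one non-negative count per cell")

  gran <- plant_granules(cells, counts, diameter_range, pixel_size,
                         height, width)
  n_g <- nrow(gran)
  gran$recruiting <- if (n_g) as.logical(rbinom(n_g, 1, recruit_fraction))
                     else logical(0)
  gran$amplitude_A <- rep(amplitude_A, n_g)

  # noiseless channel A
  base_A <- matrix(0, height, width)
  base_A[mask > 0] <- baseline_A
  spotsA <- render_spots(height, width, gran, gran$amplitude_A)
  chanA0 <- base_A + spotsA

  # channel B: solve recruiting amplitudes per cell for the planted fold
  gran$amplitude_B <- rep(0, n_g)
  base_B <- matrix(0, height, width)
  base_B[mask > 0] <- baseline_B
  if (n_g) {
    for (ci in seq_len(n_cells)) {
      idx <- which(gran$cell_id == ci & gran$recruiting)
      if (!length(idx)) next
      gran$amplitude_B[idx] <- solve_recruit_amplitudes(
        gran[idx, , drop = FALSE], mask, ci, baseline_B, enrichment_fold,
        pixel_size)
    }
  }
  chanB0 <- base_B + render_spots(height, width, gran, gran$amplitude_B)

  # illumination field
  illum <- synth_illumination(height, width, illum_order, illum_magnitude)

  degrade <- function(img) {
    out <- illum$field * img + autofluorescence
    if (noise) {
      out <- rpois(length(out), lambda = pmax(out, 0) * photon_scale) /
        photon_scale
      out <- out + rnorm(length(out), 0, read_noise_sd)
      out <- matrix(pmax(out, 0), height, width)
    }
    out
  }
  fi <- field_image(list(A = degrade(chanA0), B = degrade(chanB0)),
                    pixel_size = pixel_size, cell_mask = mask,
                    metadata = list(seed = as.integer(seed)))
  list(
    image = fi,
    truth = list(
      granules = gran,
      planted_enrichment = enrichment_fold,
      illumination_coeffs = illum$coeffs,
      illumination = illum$field,
      cell_mask = mask,
      noiseless = list(A = chanA0, B = chanB0),
      seed = as.integer(seed)))
}

# place non-overlapping ellipses fully inside the frame
place_cells <- function(width, height, n_cells, axis_range) {
  cells <- list()
  tries <- 0L
  while (length(cells) < n_cells) {
    tries <- tries + 1L
    if (tries > 5000L)
      gk_stop("could not place cells without overlap; reduce n_cells or size")
    a <- runif(1, axis_range[1], axis_range[2])
    b <- runif(1, axis_range[1], axis_range[2])
    theta <- runif(1, 0, pi)
    r <- max(a, b)
    cy <- runif(1, r + 2, height - r - 2)
    cx <- runif(1, r + 2, width - r - 2)
    ok <- TRUE
    for (cl in cells) {
      if (sqrt((cy - cl$cy)^2 + (cx - cl$cx)^2) <
          r + max(cl$a, cl$b) + 2) { ok <- FALSE; break }
    }
    if (ok) cells[[length(cells) + 1L]] <-
        list(cy = cy, cx = cx, a = a, b = b, theta = theta)
  }
  cells
}

# logical index of pixels inside an ellipse, optionally shrunk by margin
ellipse_pixels <- function(height, width, cl, margin = 0) {
  rows <- matrix(seq_len(height), height, width)
  cols <- matrix(seq_len(width), height, width, byrow = TRUE)
  dy <- rows - cl$cy; dx <- cols - cl$cx
  u <- dx * cos(cl$theta) + dy * sin(cl$theta)
  v <- -dx * sin(cl$theta) + dy * cos(cl$theta)
  a <- max(cl$a - margin, 1); b <- max(cl$b - margin, 1)
  (u / a)^2 + (v / b)^2 <= 1
}

point_in_ellipse <- function(y, x, cl, margin = 0) {
  dy <- y - cl$cy; dx <- x - cl$cx
  u <- dx * cos(cl$theta) + dy * sin(cl$theta)
  v <- -dx * sin(cl$theta) + dy * cos(cl$theta)
  a <- max(cl$a - margin, 1); b <- max(cl$b - margin, 1)
  (u / a)^2 + (v / b)^2 <= 1
}

# rejection-sample granule centres: inside the (margin-shrunk) cell,
# min centre separation = sum of radii + 2 px so spots stay resolvable
plant_granules <- function(cells, counts, diameter_range, pixel_size,
                           height, width) {
  rows <- integer(0); out <- list()
  for (ci in seq_along(cells)) {
    cl <- cells[[ci]]
    placed_y <- numeric(0); placed_x <- numeric(0); placed_r <- numeric(0)
    diams <- numeric(0)
    for (g in seq_len(counts[ci])) {
      d_um <- runif(1, diameter_range[1], diameter_range[2])
      r_px <- d_um / 2 / pixel_size
      margin <- r_px + 3
      ok <- FALSE
      for (try in 1:500) {
        y <- runif(1, cl$cy - max(cl$a, cl$b), cl$cy + max(cl$a, cl$b))
        x <- runif(1, cl$cx - max(cl$a, cl$b), cl$cx + max(cl$a, cl$b))
        if (!point_in_ellipse(y, x, cl, margin)) next
        if (length(placed_y) &&
            any(sqrt((placed_y - y)^2 + (placed_x - x)^2) <
                2 * (placed_r + r_px) + 4)) next
        ok <- TRUE
        break
      }
      if (!ok) {
        warning(sprintf("cell %d: placed %d of %d granules (crowded)",
                        ci, length(placed_y), counts[ci]), call. = FALSE)
        break
      }
      placed_y <- c(placed_y, y); placed_x <- c(placed_x, x)
      placed_r <- c(placed_r, r_px); diams <- c(diams, d_um)
    }
    if (length(placed_y))
      out[[length(out) + 1L]] <- data.frame(
        cell_id = ci, row_px = placed_y, col_px = placed_x,
        diameter_um = diams, sigma_px = diams / 2.355 / pixel_size)
  }
  if (!length(out))
    return(data.frame(cell_id = integer(0), row_px = numeric(0),
                      col_px = numeric(0), diameter_um = numeric(0),
                      sigma_px = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# additive rendering of Gaussian spots (sigma = FWHM/2.355)
render_spots <- function(height, width, gran, amplitudes) {
  img <- matrix(0, height, width)
  if (!nrow(gran)) return(img)
  for (g in seq_len(nrow(gran))) {
    if (amplitudes[g] == 0) next
    sp <- unit_spot(gran$row_px[g], gran$col_px[g], gran$sigma_px[g],
                    height, width)
    img[sp$idx] <- img[sp$idx] + amplitudes[g] * sp$val
  }
  img
}

# evaluate a unit-peak Gaussian on its support window
unit_spot <- function(cy, cx, sigma_px, height, width) {
  w <- ceiling(4 * sigma_px)
  r0 <- max(1L, floor(cy - w)); r1 <- min(height, ceiling(cy + w))
  c0 <- max(1L, floor(cx - w)); c1 <- min(width, ceiling(cx + w))
  rr <- r0:r1; cc <- c0:c1
  dy <- matrix(rr - cy, length(rr), length(cc))
  dx <- matrix(cc - cx, length(rr), length(cc), byrow = TRUE)
  val <- exp(-(dy^2 + dx^2) / (2 * sigma_px^2))
  idx <- as.vector(outer(rr, (cc - 1L) * height, `+`))
  list(idx = idx, val = as.vector(val))
}

# per-cell linear solve: amplitudes such that (b + a_k m_k) / cell_mean
# equals the planted fold, where m_k is the unit-spot mean over the
# granule's half-maximum disk and S_k its sum over the cell
solve_recruit_amplitudes <- function(gran, mask, cell_id, baseline, fold,
                                     pixel_size) {
  cell_idx <- which(mask == cell_id)
  n_pix <- length(cell_idx)
  height <- nrow(mask); width <- ncol(mask)
  k <- nrow(gran)
  m <- numeric(k); s <- numeric(k)
  for (g in seq_len(k)) {
    sp <- unit_spot(gran$row_px[g], gran$col_px[g], gran$sigma_px[g],
                    height, width)
    in_cell <- sp$idx %in% cell_idx
    s[g] <- sum(sp$val[in_cell])
    disk <- granule_disk_idx(gran$row_px[g], gran$col_px[g],
                             gran$diameter_um[g] / 2 / pixel_size,
                             height, width)
    m[g] <- mean(sp$val[match(disk, sp$idx)], na.rm = TRUE)
  }
  R <- sum(s / m)
  if (fold * R / n_pix >= 1)
    gk_stop("enrichment fold infeasible at this granule density")
  mu <- baseline * (1 - R / n_pix) / (1 - fold * R / n_pix)
  excess <- fold * mu - baseline
  excess / m
}

#' Pixel indices of a granule's half-maximum disk
#'
#' Pixels whose centre lies within `radius_px` of the granule centre;
#' the ground-truth pixel set against which detected pixel sets and
#' planted enrichment are defined.
#' @keywords internal
granule_disk_idx <- function(cy, cx, radius_px, height, width) {
  r0 <- max(1L, floor(cy - radius_px)); r1 <- min(height, ceiling(cy + radius_px))
  c0 <- max(1L, floor(cx - radius_px)); c1 <- min(width, ceiling(cx + radius_px))
  rr <- r0:r1; cc <- c0:c1
  dy <- matrix(rr - cy, length(rr), length(cc))
  dx <- matrix(cc - cx, length(rr), length(cc), byrow = TRUE)
  keep <- (dy^2 + dx^2) <= radius_px^2
  idx <- as.vector(outer(rr, (cc - 1L) * height, `+`))
  idx[as.vector(keep)]
}

# exponentiated low-order polynomial field, strictly positive, mean 1
synth_illumination <- function(height, width, order, magnitude) {
  u <- matrix(seq(-1, 1, length.out = width), height, width, byrow = TRUE)
  v <- matrix(seq(-1, 1, length.out = height), height, width)
  terms <- list(); nm <- character(0)
  for (i in 0:order) for (j in 0:order) {
    if (i + j == 0 || i + j > order) next
    terms[[length(terms) + 1L]] <- u^i * v^j
    nm <- c(nm, sprintf("u%dv%d", i, j))
  }
  if (magnitude == 0 || !length(terms)) {
    return(list(field = matrix(1, height, width),
                coeffs = setNames(numeric(length(terms)), nm)))
  }
  coeffs <- runif(length(terms), -1, 1)
  p <- Reduce(`+`, Map(`*`, terms, coeffs))
  scale <- log1p(magnitude) / max(abs(p))
  coeffs <- coeffs * scale
  p <- p * scale
  field <- exp(p)
  list(field = field / mean(field), coeffs = setNames(coeffs, nm))
}

#' Ground-truth GranuleSet
#'
#' Converts planted granules into a `granule_set` whose pixel sets are
#' the half-maximum disks of the rendered Gaussians.  This is the
#' oracle-side object for verifying colocalization and enrichment
#' computations against planted values independently of segmentation.
#'
#' @param sf the list returned by [synth_field_image()].
#' @param channel label recorded on the set (`"A"` or `"B"`).
#' @param which `"all"`, or `"recruiting"` / `"nonrecruiting"` to subset.
#' @param image_id identifier carried into the set.
#' @return a `granule_set` (see [segment_granules()]).
#' @export
truth_granule_set <- function(sf, channel = "A", which = "all",
                              image_id = "truth") {
  gran <- sf$truth$granules
  keep <- switch(which,
                 all = rep(TRUE, nrow(gran)),
                 recruiting = gran$recruiting,
                 nonrecruiting = !gran$recruiting,
                 gk_stop("`which` must be all/recruiting/nonrecruiting"))
  gran <- gran[keep, , drop = FALSE]
  mask <- sf$truth$cell_mask
  h <- nrow(mask); w <- ncol(mask)
  px <- sf$image$pixel_size
  psets <- lapply(seq_len(nrow(gran)), function(g)
    granule_disk_idx(gran$row_px[g], gran$col_px[g],
                     gran$diameter_um[g] / 2 / px, h, w))
  areas <- vapply(psets, length, integer(1))
  df <- data.frame(granule_id = seq_len(nrow(gran)),
                   cell_id = gran$cell_id,
                   row_px = gran$row_px, col_px = gran$col_px,
                   area_px2 = areas,
                   eq_diam_um = 2 * sqrt(areas / pi) * px,
                   mean_intensity = NA_real_)
  counts <- table(factor(df$cell_id,
                         levels = sort(unique(as.vector(mask[mask > 0])))))
  structure(df, pixel_sets = psets, gate = c(0, Inf), threshold = NA_real_,
            channel = channel, image_id = image_id, pixel_size = px,
            cell_granule_counts = setNames(as.integer(counts),
                                           names(counts)),
            dim_px = dim(mask),
            class = c("granule_set", "data.frame"))
}
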