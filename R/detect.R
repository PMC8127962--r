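#' Otsu threshold of an intensity sample
#'
#' Returns the level `t` maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` of the split `{x <= t}` / `{x > t}`, with
#' candidates taken over the observed distinct levels and ties broken
#' by the lowest maximizing level.
#'
#' @param x numeric vector (or matrix) of intensities, or a named
#'   histogram given as `list(levels =, counts =)`.
#' @return the threshold, an observed intensity level.
#' @examples
#' otsu_threshold(c(rep(0, 5), rep(10, 5)))  # 0
#' @export
otsu_threshold <- function(x) {
  if (is.list(x)) {
    levels <- x$levels; counts <- as.numeric(x$counts)
    o <- order(levels); levels <- levels[o]; counts <- counts[o]
  } else {
    x <- as.vector(x)
    x <- x[is.finite(x)]
    # exact unique levels + counts (table() would round-trip values
    # through strings and lose ulps, breaking scale equivariance)
    xs <- sort(x)
    starts <- which(!duplicated(xs))
    levels <- xs[starts]
    counts <- diff(c(starts, length(xs) + 1L))
  }
  if (length(levels) < 2L) gk_stop("degenerate histogram")
  n <- sum(counts)
  # cumulative class stats over candidate thresholds t = levels[i],
  # class 0 = {x <= t}; the last level cannot be a threshold
  c0 <- cumsum(counts)
  s0 <- cumsum(counts * levels)
  total <- s0[length(s0)]
  i <- seq_len(length(levels) - 1L)
  w0 <- c0[i] / n
  w1 <- 1 - w0
  mu0 <- s0[i] / c0[i]
  mu1 <- (total - s0[i]) / (n - c0[i])
  bcv <- w0 * w1 * (mu0 - mu1)^2
  levels[i][which.max(bcv)]  # which.max takes the first (lowest) maximizer
}

#' Segment granules in one channel of a FieldImage
#'
#' Reproduces puncta feature-finding: Otsu threshold over within-cell
#' pixels (per image by default, per cell optionally), 8-connected
#' components, removal of components touching the image border or
#' spanning two cells, and an inclusive equivalent-diameter gate
#' (default 0.4--2 um).
#'
#' @param fi a corrected [field_image()] with a cell mask.
#' @param channel channel name (default `"A"`, the granule marker).
#' @param gate inclusive `c(min, max)` equivalent-diameter gate in
#'   micrometres.
#' @param per_cell logical; threshold each cell separately instead of
#'   once per image.
#' @param image_id identifier carried into the output.
#' @return a `granule_set`: a data frame with one row per granule
#'   (`granule_id`, `cell_id`, `row_px`, `col_px` centroid, `area_px2`,
#'   `eq_diam_um`, `mean_intensity`) and attributes `pixel_sets` (list
#'   of linear pixel indices), `gate`, `threshold`, `channel`,
#'   `image_id`, `pixel_size`, `cell_granule_counts`, `dim`.
#' @examples
#' sf <- synth_field_image(n_cells = 2, granules_per_cell = 4, seed = 2)
#' gs <- segment_granules(correct_image(sf$image), "A")
#' nrow(gs)
#' @export
segment_granules <- function(fi, channel = "A", gate = c(0.4, 2.0),
                             per_cell = FALSE, image_id = "img1") {
  stopifnot(inherits(fi, "field_image"))
  if (!channel %in% names(fi$channels))
    gk_stop(sprintf("no channel named '%s'", channel))
  if (length(gate) != 2L || gate[1] > gate[2] || gate[1] < 0)
    gk_stop("`gate` must be an increasing non-negative pair (um)")
  img <- fi$channels[[channel]]
  mask <- fi$cell_mask
  if (!any(mask > 0)) gk_stop("empty cell mask")
  cells <- sort(setdiff(unique(as.vector(mask)), 0L))

  fg <- matrix(FALSE, nrow(img), ncol(img))
  thresholds <- c()
  if (per_cell) {
    for (ci in cells) {
      px <- img[mask == ci]
      th <- tryCatch(otsu_threshold(px), granulekit_error = function(e) NA)
      if (is.na(th)) {
        warning(sprintf("cell %d: degenerate threshold, 0 granules", ci),
                call. = FALSE)
        next
      }
      fg[mask == ci & img > th] <- TRUE
      thresholds[as.character(ci)] <- th
    }
  } else {
    px <- img[mask > 0]
    th <- tryCatch(otsu_threshold(px), granulekit_error = function(e) NA)
    if (is.na(th)) {
      warning("degenerate image threshold, 0 granules", call. = FALSE)
    } else {
      fg <- mask > 0 & img > th
      thresholds <- th
    }
  }

  lab <- .label_components8(fg)
  n_comp <- max(lab)
  rows <- list()
  pixel_sets <- list()
  if (n_comp > 0) {
    h <- nrow(img); w <- ncol(img)
    idx_all <- which(lab > 0)
    comp <- lab[idx_all]
    by_comp <- split(idx_all, comp)
    for (cidx in by_comp) {
      rr <- (cidx - 1L) %% h + 1L
      cc <- (cidx - 1L) %/% h + 1L
      if (any(rr == 1L | rr == h | cc == 1L | cc == w)) next  # border
      cell_labels <- unique(mask[cidx])
      if (length(cell_labels) != 1L) next                     # spans cells
      area <- length(cidx)
      eq_diam <- 2 * sqrt(area / pi) * fi$pixel_size
      if (eq_diam < gate[1] || eq_diam > gate[2]) next
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = cell_labels, row_px = mean(rr), col_px = mean(cc),
        area_px2 = area, eq_diam_um = eq_diam,
        mean_intensity = mean(img[cidx]))
      pixel_sets[[length(pixel_sets) + 1L]] <- cidx
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = integer(0), row_px = numeric(0),
               col_px = numeric(0), area_px2 = numeric(0),
               eq_diam_um = numeric(0), mean_intensity = numeric(0))
  o <- order(out$cell_id, out$row_px, out$col_px)
  out <- out[o, , drop = FALSE]
  pixel_sets <- pixel_sets[o]
  rownames(out) <- NULL
  out <- cbind(granule_id = seq_len(nrow(out)), out)
  counts <- table(factor(out$cell_id, levels = cells))
  structure(out,
            pixel_sets = pixel_sets,
            gate = gate, threshold = thresholds, channel = channel,
            image_id = image_id, pixel_size = fi$pixel_size,
            cell_granule_counts = setNames(as.integer(counts), cells),
            dim_px = dim(img),
            class = c("granule_set", "data.frame"))
}
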