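#' Match granules between two channels by centroid distance
#'
#' Object-based colocalization: within each cell, all pairwise centroid
#' distances between channel-A and channel-B granules are computed and a
#' one-to-one matching is built greedily, always accepting the globally
#' smallest remaining distance not exceeding `cutoff`.  Ties are broken
#' deterministically by (cell_id, A_id, B_id).
#'
#' @param set_A,set_B `granule_set` objects from [segment_granules()] on
#'   the same image (same `image_id` and cell labeling).
#' @param cutoff maximum centroid distance for a colocalization event,
#'   micrometres.  The default 0.5 um is sub-granule-scale proximity
#'   (a quarter of the maximum gate diameter).
#' @return a `coloc_result`: list with `matches` (data frame: cell_id,
#'   A_id, B_id, distance_um), `per_cell` (cell_id, n_A, n_B,
#'   n_matched, fraction), `cutoff`, `image_id`.
#' @examples
#' sf <- synth_field_image(n_cells = 2, granules_per_cell = 4, seed = 3)
#' fi <- correct_image(sf$image)
#' cr <- match_granules(segment_granules(fi, "A"), segment_granules(fi, "B"))
#' cr$per_cell
#' @export
match_granules <- function(set_A, set_B, cutoff = 0.5) {
  stopifnot(inherits(set_A, "granule_set"), inherits(set_B, "granule_set"))
  gk_check_positive(cutoff, "cutoff")
  if (!identical(attr(set_A, "image_id"), attr(set_B, "image_id")))
    gk_stop("granule sets come from different images")
  px <- attr(set_A, "pixel_size")
  cells <- union(names(attr(set_A, "cell_granule_counts")),
                 names(attr(set_B, "cell_granule_counts")))
  pairs <- list()
  for (ci in cells) {
    ia <- which(set_A$cell_id == as.integer(ci))
    ib <- which(set_B$cell_id == as.integer(ci))
    if (!length(ia) || !length(ib)) next
    d <- sqrt(outer(set_A$row_px[ia], set_B$row_px[ib], `-`)^2 +
              outer(set_A$col_px[ia], set_B$col_px[ib], `-`)^2) * px
    keep <- which(d <= cutoff, arr.ind = TRUE)
    if (!nrow(keep)) next
    pairs[[length(pairs) + 1L]] <- data.frame(
      cell_id = as.integer(ci),
      A_id = set_A$granule_id[ia[keep[, 1]]],
      B_id = set_B$granule_id[ib[keep[, 2]]],
      distance_um = d[keep])
  }
  matches <- if (length(pairs)) {
    cand <- do.call(rbind, pairs)
    cand <- cand[order(cand$distance_um, cand$cell_id, cand$A_id, cand$B_id),
                 , drop = FALSE]
    used_a <- integer(0); used_b <- integer(0); take <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (cand$A_id[i] %in% used_a || cand$B_id[i] %in% used_b) next
      take[i] <- TRUE
      used_a <- c(used_a, cand$A_id[i]); used_b <- c(used_b, cand$B_id[i])
    }
    out <- cand[take, , drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    data.frame(cell_id = integer(0), A_id = integer(0), B_id = integer(0),
               distance_um = numeric(0))
  }
  counts_A <- attr(set_A, "cell_granule_counts")
  counts_B <- attr(set_B, "cell_granule_counts")
  all_cells <- sort(unique(as.integer(union(names(counts_A), names(counts_B)))))
  per_cell <- data.frame(
    cell_id = all_cells,
    n_A = as.integer(counts_A[as.character(all_cells)]),
    n_B = as.integer(counts_B[as.character(all_cells)]),
    n_matched = vapply(all_cells, function(ci)
      sum(matches$cell_id == ci), integer(1)))
  per_cell$n_A[is.na(per_cell$n_A)] <- 0L
  per_cell$n_B[is.na(per_cell$n_B)] <- 0L
  per_cell$fraction <- ifelse(per_cell$n_A > 0,
                              per_cell$n_matched / per_cell$n_A, NA_real_)
  structure(list(matches = matches, per_cell = per_cell, cutoff = cutoff,
                 image_id = attr(set_A, "image_id")),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %s: %d matches over %d cells (cutoff %.2f um)\n",
              x$image_id, nrow(x$matches), nrow(x$per_cell), x$cutoff))
  invisible(x)
}

#' Percent colocalization from a match result
#'
#' `100 * matched / total` over the reference channel, per cell and
#' pooled over cells.  Cells with zero reference granules are excluded
#' from per-cell values and reported in `n_excluded`.
#'
#' @param result a `coloc_result` from [match_granules()].
#' @param reference which channel's granules form the denominator,
#'   `"A"` (default) or `"B"`.
#' @return list with `per_cell` (cell_id, percent), `pooled` (percent
#'   over all reference granules), `n_excluded`.
#' @export
colocalization_fraction <- function(result, reference = c("A", "B")) {
  stopifnot(inherits(result, "coloc_result"))
  reference <- match.arg(reference)
  pc <- result$per_cell
  n_ref <- if (reference == "A") pc$n_A else pc$n_B
  keep <- n_ref > 0
  if (!any(keep)) gk_stop("all cells have zero reference granules")
  per_cell <- data.frame(cell_id = pc$cell_id[keep],
                         percent = 100 * pc$n_matched[keep] / n_ref[keep])
  list(per_cell = per_cell,
       pooled = 100 * sum(pc$n_matched[keep]) / sum(n_ref[keep]),
       n_excluded = sum(!keep))
}

#' Fold enrichment of a signal channel at granules
#'
#' For each granule, the mean signal-channel intensity over the
#' granule's pixels divided by the mean over the whole area of its cell
#' (granule pixels included).  Fold 1 means no enrichment.
#'
#' @param granules a `granule_set` (typically detected on the granule
#'   channel) carrying pixel sets.
#' @param signal_channel 2D intensity matrix of the signaling-protein
#'   channel (corrected).
#' @param cell_mask label matrix; defaults to the mask recorded at
#'   detection if the granule set came from the same image geometry.
#' @param exclude_granule_pixels logical; drop granule pixels from the
#'   whole-cell denominator (off by default).
#' @return an `enrichment_result`: list with `per_granule` (granule_id,
#'   cell_id, fold), `per_cell` (cell_id, n, mean_fold, sem_fold), and
#'   `summary` (n, mean, sem over granules).
#' @examples
#' sf <- synth_field_image(n_cells = 2, granules_per_cell = 4,
#'                         enrichment_fold = 3, seed = 4)
#' fi <- correct_image(sf$image)
#' gs <- segment_granules(fi, "A")
#' fe <- fold_enrichment(gs, fi$channels$B, fi$cell_mask)
#' fe$summary
#' @export
fold_enrichment <- function(granules, signal_channel, cell_mask,
                            exclude_granule_pixels = FALSE) {
  stopifnot(inherits(granules, "granule_set"))
  if (!is.matrix(signal_channel) ||
      !identical(dim(signal_channel), attr(granules, "dim_px")))
    gk_stop("`signal_channel` dimensions do not match the granule set")
  if (!identical(dim(cell_mask), dim(signal_channel)))
    gk_stop("`cell_mask` dimensions do not match the signal channel")
  psets <- attr(granules, "pixel_sets")
  n <- nrow(granules)
  fold <- numeric(n)
  cell_means <- new.env()
  for (g in seq_len(n)) {
    ci <- granules$cell_id[g]
    key <- as.character(ci)
    if (is.null(cell_means[[key]])) {
      cpix <- which(cell_mask == ci)
      if (exclude_granule_pixels) {
        gran_pix <- unlist(psets[granules$cell_id == ci])
        cpix <- setdiff(cpix, gran_pix)
      }
      mu <- mean(signal_channel[cpix])
      if (!is.finite(mu) || mu <= 0)
        gk_stop(sprintf("cell %d: zero whole-cell mean", ci))
      cell_means[[key]] <- mu
    }
    fold[g] <- mean(signal_channel[psets[[g]]]) / cell_means[[key]]
  }
  per_granule <- data.frame(granule_id = granules$granule_id,
                            cell_id = granules$cell_id, fold = fold)
  agg <- split(fold, granules$cell_id)
  per_cell <- data.frame(
    cell_id = as.integer(names(agg)),
    n = vapply(agg, length, integer(1)),
    mean_fold = vapply(agg, mean, numeric(1)),
    sem_fold = vapply(agg, function(x)
      if (length(x) >= 2) sem(x) else NA_real_, numeric(1)))
  rownames(per_cell) <- NULL
  structure(list(
    per_granule = per_granule, per_cell = per_cell,
    summary = list(n = n, mean = mean(fold),
                   sem = if (n >= 2) sem(fold) else NA_real_)),
    class = "enrichment_result")
}
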