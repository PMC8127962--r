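#' Build per-cell records from a granule table
#'
#' Collapses a granule-level table (e.g. rows of a `granule_set`, or
#' the detect CSV) into one row per cell with its granule count and
#' diameter list, the input to the phenotype summaries.
#'
#' @param granules data frame with columns `cell_id`, `eq_diam_um`, and
#'   optionally `image_id`.
#' @param all_cells optional data frame (`image_id`, `cell_id`) listing
#'   every scored cell so that granule-free cells appear with count 0.
#' @param condition condition label attached to every record.
#' @param replicate replicate label (independent experiment).
#' @return data frame with columns `image_id`, `cell_id`, `condition`,
#'   `replicate`, `granule_count`, and list-column `diameters_um`.
#' @export
cell_records <- function(granules, all_cells = NULL, condition = "cond1",
                         replicate = 1L) {
  if (is.null(granules$image_id)) granules$image_id <- "img1"
  key <- interaction(granules$image_id, granules$cell_id, drop = TRUE,
                     sep = "\r")
  counts <- tapply(granules$cell_id, key, length)
  diams <- split(granules$eq_diam_um, key)
  ids <- do.call(rbind, strsplit(names(counts), "\r", fixed = TRUE))
  rec <- data.frame(image_id = ids[, 1],
                    cell_id = as.integer(ids[, 2]),
                    condition = condition, replicate = replicate,
                    granule_count = as.integer(counts))
  rec$diameters_um <- unname(diams)
  if (!is.null(all_cells)) {
    have <- paste(rec$image_id, rec$cell_id)
    missing <- !(paste(all_cells$image_id, all_cells$cell_id) %in% have)
    if (any(missing)) {
      extra <- data.frame(image_id = all_cells$image_id[missing],
                          cell_id = as.integer(all_cells$cell_id[missing]),
                          condition = condition, replicate = replicate,
                          granule_count = 0L)
      extra$diameters_um <- rep(list(numeric(0)), sum(missing))
      rec <- rbind(rec, extra)
    }
  }
  rec[order(rec$image_id, rec$cell_id), , drop = FALSE]
}

#' Percent of cells containing granules
#'
#' A cell is granule-positive when it holds at least `threshold`
#' granules (default 6, the scoring criterion for scanned fields).
#' The percentage is computed per replicate within each condition, then
#' averaged; the SEM is taken across replicates, matching the error-bar
#' convention of replicate-level experiments.
#'
#' @param cells data frame of cell records (see [cell_records()]): needs
#'   `condition`, `replicate`, `granule_count`.
#' @param threshold minimum granule count to score positive.
#' @return data frame per condition: `condition`, `n_cells`,
#'   `n_replicates`, `percent` (mean of replicate percentages),
#'   `sem` (across replicates; NA with one replicate).
#' @examples
#' cells <- data.frame(condition = "v1", replicate = 1,
#'                     granule_count = c(7, 6, 5, 0))
#' granule_positive_fraction(cells)$percent  # 50
#' @export
granule_positive_fraction <- function(cells, threshold = 6L) {
  if (!nrow(cells)) gk_stop("no cells given")
  if (threshold < 0) gk_stop("`threshold` must be >= 0")
  out <- lapply(split(cells, cells$condition), function(df) {
    reps <- split(df, df$replicate)
    pct <- vapply(reps, function(r)
      100 * mean(r$granule_count >= threshold), numeric(1))
    data.frame(condition = df$condition[1], n_cells = nrow(df),
               n_replicates = length(reps), percent = mean(pct),
               sem = if (length(pct) >= 2) sem(pct) else NA_real_)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Granule persistence across a treatment
#'
#' Ratio of granule counts after versus before treatment, per paired
#' field (e.g. the same field of view imaged before and 5 min after
#' 1,6-hexanediol).  Fields with zero pre-treatment granules are
#' excluded and reported.  Ratios above 1 are kept but flagged.
#'
#' @param pre,post data frames with columns `image_id` and
#'   `granule_count` (one row per field, or per cell -- counts are
#'   summed within `image_id`).
#' @return list with `per_field` (image_id, n_pre, n_post, ratio,
#'   flagged_gt1), `pooled` (mean ratio), `sem`, `n_excluded`.
#' @examples
#' pre <- data.frame(image_id = "f1", granule_count = 10)
#' post <- data.frame(image_id = "f1", granule_count = 5)
#' persistence_ratio(pre, post)$pooled  # 0.5
#' @export
persistence_ratio <- function(pre, post) {
  tot <- function(df) tapply(df$granule_count, df$image_id, sum)
  a <- tot(pre); b <- tot(post)
  fields <- intersect(names(a), names(b))
  if (!length(fields)) gk_stop("no paired fields between pre and post")
  n_pre <- as.numeric(a[fields]); n_post <- as.numeric(b[fields])
  excl <- n_pre == 0
  if (any(excl))
    message(sprintf("excluding %d field(s) with zero pre-treatment granules",
                    sum(excl)))
  fields <- fields[!excl]; n_pre <- n_pre[!excl]; n_post <- n_post[!excl]
  if (!length(fields)) gk_stop("all fields had zero pre-treatment granules")
  ratio <- n_post / n_pre
  per_field <- data.frame(image_id = fields, n_pre = n_pre, n_post = n_post,
                          ratio = ratio, flagged_gt1 = ratio > 1)
  list(per_field = per_field, pooled = mean(ratio),
       sem = if (length(ratio) >= 2) sem(ratio) else NA_real_,
       n_excluded = sum(excl))
}

#' Granule size and per-cell count distributions
#'
#' @param cells cell records (see [cell_records()]) with list-column
#'   `diameters_um` and `granule_count`.
#' @return data frame per condition: median diameter (um), diameter
#'   quartiles, and the median/quartiles of the per-cell granule count.
#' @export
granule_size_stats <- function(cells) {
  if (!nrow(cells) || sum(cells$granule_count) == 0)
    gk_stop("no granules to summarize")
  out <- lapply(split(cells, cells$condition), function(df) {
    d <- unlist(df$diameters_um)
    qd <- quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
    qc <- quantile(df$granule_count, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(condition = df$condition[1], n_cells = nrow(df),
               n_granules = length(d),
               diam_q1 = qd[1], median_diam_um = qd[2], diam_q3 = qd[3],
               count_q1 = qc[1], median_count = qc[2], count_q3 = qc[3])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
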