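#' Pipeline configuration
#'
#' All tunable parameters of the imaging, FRAP, and biochemistry tracks
#' in one validated list; serializes losslessly to YAML.
#'
#' @param pixel_size micrometres per pixel.
#' @param gate_min,gate_max equivalent-diameter gate, micrometres.
#' @param coloc_cutoff centroid-distance cutoff, micrometres.
#' @param positive_threshold granule count for a granule-positive cell.
#' @param frap_eval_time mobile-fraction evaluation time, seconds.
#' @param alpha significance level.
#' @param seed integer seed for every stochastic step.
#' @param per_cell_threshold logical; per-cell Otsu thresholding.
#' @param poly_order illumination polynomial order.
#' @param autofluorescence scalar background subtracted after
#'   flat-fielding.
#' @param synth named list of overrides passed to [synth_field_image()].
#' @param n_images number of fields to generate/process.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(pixel_size = 0.1, gate_min = 0.4, gate_max = 2.0,
                            coloc_cutoff = 0.5, positive_threshold = 6L,
                            frap_eval_time = 60, alpha = 0.05, seed = 1L,
                            per_cell_threshold = FALSE, poly_order = 2L,
                            autofluorescence = 0, synth = list(),
                            n_images = 3L) {
  cfg <- list(pixel_size = pixel_size, gate_min = gate_min,
              gate_max = gate_max, coloc_cutoff = coloc_cutoff,
              positive_threshold = as.integer(positive_threshold),
              frap_eval_time = frap_eval_time, alpha = alpha,
              seed = as.integer(seed),
              per_cell_threshold = isTRUE(per_cell_threshold),
              poly_order = as.integer(poly_order),
              autofluorescence = autofluorescence,
              synth = synth, n_images = as.integer(n_images))
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(cfg) {
  for (nm in c("pixel_size", "gate_min", "gate_max", "coloc_cutoff",
               "frap_eval_time", "alpha"))
    gk_check_positive(cfg[[nm]], nm)
  if (cfg$gate_min > cfg$gate_max) gk_stop("gate_min exceeds gate_max")
  if (cfg$positive_threshold < 0) gk_stop("positive_threshold must be >= 0")
  if (cfg$n_images < 1) gk_stop("n_images must be >= 1")
  invisible(cfg)
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    gk_stop(sprintf("unknown config field(s): %s",
                    paste(unknown, collapse = ", ")))
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(cfg)), tmp)
  unname(tools::md5sum(tmp))
}

# CSV with an audit header line; read back with gk_read_csv
gk_write_csv <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# granulekit config_hash=%s seed=%d",
                     config_hash(cfg), cfg$seed), con)
  # drop list columns (not representable in CSV)
  df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @keywords internal
gk_read_csv <- function(path) read.csv(path, comment.char = "#")

#' Run the imaging analysis track end-to-end
#'
#' Executes correction, detection on both channels, colocalization,
#' enrichment, and phenotype summaries for a batch of fields, writing
#' one CSV per stage plus a run log.  Fields are either generated
#' synthetically (with ground truth saved alongside) or read from
#' paired TIFF files.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param input_dir directory with `*_channels.tif` / `*_mask.tif`
#'   pairs; ignored when `synth = TRUE`.
#' @param synth logical; generate `config$n_images` synthetic fields.
#' @return named list of output paths, invisibly; the summaries are
#'   also returned in `$results`.
#' @export
run_imaging_pipeline <- function(config, out_dir, input_dir = NULL,
                                 synth = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("granulekit run %s", format(Sys.time())),
                 sprintf("config_hash: %s", config_hash(config)),
                 yaml::as.yaml(unclass(config)))
  fields <- list()
  truths <- list()
  if (synth) {
    for (i in seq_len(config$n_images)) {
      args <- modifyList(
        list(pixel_size = config$pixel_size,
             seed = config$seed + i - 1L),
        config$synth)
      sf <- do.call(synth_field_image, args)
      fields[[sprintf("synth%02d", i)]] <- sf$image
      tg <- sf$truth$granules
      if (nrow(tg)) tg <- cbind(image_id = sprintf("synth%02d", i), tg)
      truths[[sprintf("synth%02d", i)]] <- tg
    }
  } else {
    if (is.null(input_dir) || !dir.exists(input_dir))
      gk_stop(sprintf("input directory not found: %s", input_dir %||% "<NULL>"),
              class = "granulekit_user_error")
    chans <- sort(list.files(input_dir, "_channels\\.tif$", full.names = TRUE))
    if (!length(chans))
      gk_stop(sprintf("no *_channels.tif images in %s", input_dir),
              class = "granulekit_user_error")
    for (cp in chans) {
      mp <- sub("_channels\\.tif$", "_mask.tif", cp)
      if (!file.exists(mp))
        gk_stop(sprintf("missing mask for %s (expected %s)", cp, mp),
                class = "granulekit_user_error")
      id <- sub("_channels\\.tif$", "", basename(cp))
      fields[[id]] <- read_field_image(cp, mp, config$pixel_size)
    }
  }

  gate <- c(config$gate_min, config$gate_max)
  all_gran <- list(); all_match <- list(); all_cells_coloc <- list()
  all_enrich <- list(); all_records <- list()
  for (id in names(fields)) {
    fi <- correct_image(fields[[id]], poly_order = config$poly_order,
                        autofluorescence = config$autofluorescence)
    gsA <- segment_granules(fi, "A", gate = gate,
                            per_cell = config$per_cell_threshold,
                            image_id = id)
    log_lines <- c(log_lines, sprintf(
      "%s: channel A threshold %s, %d granules", id,
      paste(signif(attr(gsA, "threshold"), 6), collapse = ","), nrow(gsA)))
    gdf <- as.data.frame(gsA)
    if (nrow(gdf)) {
      gdf <- cbind(image_id = id, channel = "A", gdf)
      all_gran[[id]] <- gdf
    }
    if ("B" %in% names(fi$channels)) {
      gsB <- segment_granules(fi, "B", gate = gate,
                              per_cell = config$per_cell_threshold,
                              image_id = id)
      cr <- match_granules(gsA, gsB, cutoff = config$coloc_cutoff)
      mt <- cr$matches
      if (nrow(mt)) all_match[[id]] <- cbind(image_id = id, mt)
      pc <- cr$per_cell
      pc$percent <- ifelse(pc$n_A > 0, 100 * pc$n_matched / pc$n_A, NA)
      all_cells_coloc[[id]] <- cbind(image_id = id, pc)
      if (nrow(gsA)) {
        fe <- fold_enrichment(gsA, fi$channels$B, fi$cell_mask)
        all_enrich[[id]] <- cbind(image_id = id, fe$per_granule)
      }
    }
    if (nrow(gdf)) {
      rec <- cell_records(gdf)
      all_records[[id]] <- rec[, setdiff(names(rec), "diameters_um")]
    }
  }
  paths <- list()
  emit <- function(lst, name) {
    df <- do.call(rbind, lst)
    if (is.null(df)) df <- data.frame()
    p <- file.path(out_dir, paste0(name, ".csv"))
    gk_write_csv(df, p, config)
    paths[[name]] <<- p
  }
  emit(all_gran, "granules")
  emit(all_match, "matches")
  emit(all_cells_coloc, "coloc_per_cell")
  emit(all_enrich, "enrichment")
  emit(all_records, "cells")
  if (synth) emit(truths, "ground_truth")
  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, log_path)
  paths$log <- log_path
  results <- list(
    n_granules = sum(vapply(all_gran, nrow, integer(1))),
    n_matches = sum(vapply(all_match, nrow, integer(1))))
  invisible(c(paths, list(results = results)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
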