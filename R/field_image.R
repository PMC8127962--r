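#' Construct a FieldImage
#'
#' The unit of image analysis: one or more co-registered intensity
#' channels, the physical pixel size, and a per-cell label mask
#' (0 = background, k = cell k, matching manual cell delineation).
#'
#' @param channels named list of numeric matrices, all the same size.
#'   Typical names are `"A"` (granule marker, e.g. BFP-tagged fusion
#'   oncoprotein) and `"B"` (signaling protein, e.g. GFP-tagged).
#' @param pixel_size physical pixel size in micrometres per pixel.
#' @param cell_mask integer label matrix of the same size as the channels.
#' @param metadata optional named list of acquisition tags.
#' @return an object of class `field_image`.
#' @examples
#' img <- matrix(100, 32, 32)
#' mask <- matrix(1L, 32, 32)
#' fi <- field_image(list(A = img), pixel_size = 0.1, cell_mask = mask)
#' @export
field_image <- function(channels, pixel_size, cell_mask, metadata = list()) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    gk_stop("`channels` must be a named list of matrices")
  if (!all(vapply(channels, is.matrix, logical(1))))
    gk_stop("every channel must be a numeric matrix")
  gk_check_positive(pixel_size, "pixel_size")
  d <- dim(channels[[1]])
  same <- vapply(channels, function(m) identical(dim(m), d), logical(1))
  if (!all(same)) gk_stop("all channels must share dimensions")
  if (!is.matrix(cell_mask) || !identical(dim(cell_mask), d))
    gk_stop("`cell_mask` must be a matrix matching the channel dimensions")
  if (any(vapply(channels, function(m) any(m < 0), logical(1))))
    gk_stop("channel intensities must be non-negative")
  structure(
    list(channels = channels, pixel_size = pixel_size,
         cell_mask = matrix(as.integer(cell_mask), d[1], d[2]),
         metadata = metadata),
    class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<field_image> %d x %d px (%.3g um/px), channels: %s, %d cells\n",
              d[1], d[2], x$pixel_size,
              paste(names(x$channels), collapse = ", "),
              length(setdiff(unique(as.vector(x$cell_mask)), 0L))))
  invisible(x)
}

#' Write a FieldImage to TIFF files
#'
#' Channels go to one multi-page 16-bit TIFF (page order = channel order),
#' the cell mask to a 16-bit label TIFF.
#'
#' @param fi a [field_image()].
#' @param dir output directory (created if absent).
#' @param stem file-name stem; writes `<stem>_channels.tif` and
#'   `<stem>_mask.tif`.
#' @return named character vector of the written paths, invisibly.
#' @export
write_field_image <- function(fi, dir, stem = "field") {
  stopifnot(inherits(fi, "field_image"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chan_path <- file.path(dir, paste0(stem, "_channels.tif"))
  mask_path <- file.path(dir, paste0(stem, "_mask.tif"))
  write_tiff(fi$channels, chan_path)
  write_tiff(fi$cell_mask, mask_path)
  invisible(c(channels = chan_path, mask = mask_path))
}

#' Read a FieldImage from TIFF files
#'
#' @param channels_path multi-page TIFF of channel images.
#' @param mask_path label TIFF of the cell mask.
#' @param pixel_size micrometres per pixel.
#' @param channel_names names for the pages (default A, B, ...).
#' @return a [field_image()].
#' @export
read_field_image <- function(channels_path, mask_path, pixel_size,
                             channel_names = NULL) {
  pages <- read_tiff(channels_path)
  if (is.null(channel_names))
    channel_names <- LETTERS[seq_along(pages)]
  names(pages) <- channel_names
  mask <- read_tiff(mask_path)[[1]]
  field_image(pages, pixel_size = pixel_size, cell_mask = mask)
}
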