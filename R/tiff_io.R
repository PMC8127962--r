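#' Write matrices as a 16-bit grayscale multi-page TIFF
#'
#' Minimal baseline-TIFF writer used for channel images and label masks:
#' little-endian, uncompressed, one strip per page, 16-bit unsigned
#' grayscale.  Values are clamped to \[0, 65535\] and rounded.
#'
#' @param images a numeric matrix or a list of numeric matrices (pages).
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_tiff()]
#' @export
write_tiff <- function(images, path) {
  if (is.matrix(images)) images <- list(images)
  if (!length(images) || !all(vapply(images, is.matrix, logical(1))))
    gk_stop("`images` must be a matrix or list of matrices")
  con <- file(path, "wb")
  on.exit(close(con))
  wle <- function(x, size) writeBin(as.integer(x), con, size = size,
                                    endian = "little")
  writeBin(charToRaw("II"), con)
  wle(42L, 2)
  # layout: header (8) | page1 pixels | page1 IFD | page2 pixels | ...
  n_entries <- 10L
  ifd_size <- 2L + n_entries * 12L + 4L
  offset <- 8L
  n <- length(images)
  first_ifd <- offset + 2L * nrow(images[[1]]) * ncol(images[[1]])
  wle(first_ifd, 4)
  for (i in seq_len(n)) {
    img <- images[[i]]
    h <- nrow(img); w <- ncol(img)
    nbytes <- 2L * h * w
    data_off <- offset
    ifd_off <- data_off + nbytes
    px <- as.integer(round(pmin(pmax(t(img), 0), 65535)))  # row-major
    writeBin(px, con, size = 2, endian = "little")
    # IFD
    wle(n_entries, 2)
    entry <- function(tag, type, count, value) {
      wle(tag, 2); wle(type, 2); wle(count, 4)
      if (type == 3L) { wle(value, 2); wle(0L, 2) } else wle(value, 4)
    }
    entry(256L, 4L, 1L, w)              # ImageWidth
    entry(257L, 4L, 1L, h)              # ImageLength
    entry(258L, 3L, 1L, 16L)            # BitsPerSample
    entry(259L, 3L, 1L, 1L)             # Compression: none
    entry(262L, 3L, 1L, 1L)             # Photometric: BlackIsZero
    entry(273L, 4L, 1L, data_off)       # StripOffsets
    entry(277L, 3L, 1L, 1L)             # SamplesPerPixel
    entry(278L, 4L, 1L, h)              # RowsPerStrip
    entry(279L, 4L, 1L, nbytes)         # StripByteCounts
    entry(339L, 3L, 1L, 1L)             # SampleFormat: unsigned int
    next_ifd <- if (i < n) {
      nxt <- images[[i + 1]]
      ifd_off + ifd_size + 2L * nrow(nxt) * ncol(nxt)
    } else 0L
    wle(next_ifd, 4)
    offset <- ifd_off + ifd_size
  }
  invisible(path)
}

#' Read an uncompressed grayscale TIFF
#'
#' Reads single-channel 8- or 16-bit uncompressed TIFF files (including
#' multi-page files written by [write_tiff()]).  Tiled, compressed, or
#' multi-sample files are rejected with an error.
#'
#' @param path file path.
#' @param pages which pages to read (default all).
#' @return a list of integer matrices, one per page.
#' @export
read_tiff <- function(path, pages = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2)
  endian <- if (identical(magic, charToRaw("II"))) "little"
            else if (identical(magic, charToRaw("MM"))) "big"
            else gk_stop("not a TIFF file: bad byte-order mark")
  rle <- function(size, n = 1, signed = TRUE)
    readBin(con, "integer", n = n, size = size, endian = endian,
            signed = signed)
  if (rle(2, signed = FALSE) != 42L) gk_stop("not a TIFF file: bad magic")
  ifd_off <- rle(4)
  out <- list()
  page <- 0L
  while (ifd_off != 0L) {
    page <- page + 1L
    seek(con, ifd_off)
    n_ent <- rle(2, signed = FALSE)
    tags <- new.env()
    for (k in seq_len(n_ent)) {
      tag <- rle(2, signed = FALSE)
      type <- rle(2, signed = FALSE)
      count <- rle(4)
      here <- seek(con)
      val <- if (type == 3L && count <= 2L) rle(2, n = count, signed = FALSE)
             else if (type %in% c(4L, 9L) && count == 1L) rle(4)
             else rle(4)  # offset to out-of-line values
      seek(con, here + 4L)
      assign(as.character(tag), list(type = type, count = count, val = val),
             envir = tags)
    }
    next_off <- rle(4)
    gettag <- function(t, default = NULL) {
      e <- mget(as.character(t), envir = tags, ifnotfound = list(NULL))[[1]]
      if (is.null(e)) default else e
    }
    need <- function(t, name) {
      e <- gettag(t)
      if (is.null(e)) gk_stop(sprintf("TIFF page %d: missing %s", page, name))
      e
    }
    w <- need(256L, "ImageWidth")$val[1]
    h <- need(257L, "ImageLength")$val[1]
    bits <- gettag(258L, list(val = 1L))$val[1]
    comp <- gettag(259L, list(val = 1L))$val[1]
    spp <- gettag(277L, list(val = 1L))$val[1]
    if (comp != 1L) gk_stop("only uncompressed TIFF is supported")
    if (spp != 1L) gk_stop("only single-sample (grayscale) TIFF is supported")
    if (!bits %in% c(8L, 16L)) gk_stop("only 8- or 16-bit TIFF is supported")
    so <- need(273L, "StripOffsets")
    sc <- need(279L, "StripByteCounts")
    read_longs <- function(e) {
      if (e$count == 1L) return(e$val[1])
      seek(con, e$val)
      size <- if (e$type == 3L) 2 else 4
      rle(size, n = e$count, signed = FALSE)
    }
    offs <- read_longs(so)
    cnts <- read_longs(sc)
    keep <- is.null(pages) || page %in% pages
    if (keep) {
      bytes <- raw(0)
      for (s in seq_along(offs)) {
        seek(con, offs[s])
        bytes <- c(bytes, readBin(con, "raw", cnts[s]))
      }
      size <- bits / 8L
      px <- readBin(bytes, "integer", n = w * h, size = size,
                    endian = endian, signed = FALSE)
      out[[length(out) + 1L]] <- t(matrix(px, nrow = w, ncol = h))
    }
    ifd_off <- next_off
  }
  out
}
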