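#' Estimate a multiplicative illumination field
#'
#' Robust polynomial surface fit to the log intensities over the given
#' mask, exponentiated and normalized to mean 1.  Bright outliers
#' (granules) are iteratively downweighted with Tukey's bisquare, so the
#' fit tracks the smooth cytosolic background rather than the puncta.
#'
#' @param image 2D intensity matrix.
#' @param mask logical or 0/1 matrix of pixels to use (default: all
#'   pixels with positive intensity).
#' @param poly_order polynomial order of the surface (default 2).
#' @param max_iter IRLS iterations.
#' @return a strictly positive matrix of the image's size with mean 1
#'   over the mask; fitted coefficients in `attr(, "coeffs")`.
#' @examples
#' img <- matrix(100, 64, 64)
#' f <- estimate_illumination_field(img)
#' range(f)  # all 1
#' @export
estimate_illumination_field <- function(image, mask = NULL, poly_order = 2,
                                        max_iter = 20) {
  if (!is.matrix(image)) gk_stop("`image` must be a matrix")
  if (is.null(mask)) mask <- image > 0
  mask <- mask & image > 0 & is.finite(image)
  n_terms <- (poly_order + 1) * (poly_order + 2) / 2
  n_use <- sum(mask)
  if (n_use < n_terms)
    gk_stop(sprintf(
      "degenerate fit: order %d needs >= %d usable pixels, got %d",
      poly_order, n_terms, n_use))
  h <- nrow(image); w <- ncol(image)
  u <- matrix(seq(-1, 1, length.out = w), h, w, byrow = TRUE)
  v <- matrix(seq(-1, 1, length.out = h), h, w)
  X <- poly_basis(u[mask], v[mask], poly_order)
  y <- log(image[mask])
  qrX <- qr(X)
  if (qrX$rank < n_terms)
    gk_stop(sprintf(
      "degenerate fit: rank %d < %d terms at order %d (%d pixels)",
      qrX$rank, n_terms, poly_order, n_use))
  beta <- qr.coef(qrX, y)
  for (it in seq_len(max_iter)) {
    res <- y - drop(X %*% beta)
    s <- median(abs(res - median(res))) * 1.4826
    if (s < 1e-12) break
    wgt <- bisquare_weight(res / s, c = 4.685)
    beta_new <- tryCatch(
      solve(crossprod(X * sqrt(wgt)), crossprod(X * wgt, y)),
      error = function(e) NULL)
    if (is.null(beta_new)) break
    if (max(abs(beta_new - beta)) < 1e-10) { beta <- drop(beta_new); break }
    beta <- drop(beta_new)
  }
  Xfull <- poly_basis(as.vector(u), as.vector(v), poly_order)
  field <- matrix(exp(drop(Xfull %*% beta)), h, w)
  field <- field / mean(field[mask])
  attr(field, "coeffs") <- beta
  field
}

poly_basis <- function(u, v, order) {
  cols <- list()
  for (i in 0:order) for (j in 0:(order - i))
    cols[[length(cols) + 1L]] <- u^i * v^j
  do.call(cbind, cols)
}

bisquare_weight <- function(r, c = 4.685) {
  w <- (1 - (r / c)^2)^2
  w[abs(r) > c] <- 0
  w
}

#' Correct a FieldImage for illumination and autofluorescence
#'
#' Applies `corrected = max(raw / illumination - autofluorescence, 0)`
#' channel by channel.  Dimensions, mask, and metadata are unchanged.
#'
#' @param fi a [field_image()].
#' @param illumination a single field matrix applied to all channels, or
#'   a named list of per-channel fields; `NULL` estimates one per
#'   channel with [estimate_illumination_field()] over the cell mask.
#' @param autofluorescence scalar, named per-channel numeric, or matrix
#'   subtracted after flat-fielding (default 0).
#' @param poly_order order used when estimating (default 2).
#' @return the corrected [field_image()]; applied fields are recorded in
#'   `metadata$correction`.
#' @export
correct_image <- function(fi, illumination = NULL, autofluorescence = 0,
                          poly_order = 2) {
  stopifnot(inherits(fi, "field_image"))
  nms <- names(fi$channels)
  if (is.null(illumination)) {
    illumination <- lapply(fi$channels, function(ch)
      estimate_illumination_field(ch, mask = fi$cell_mask > 0,
                                  poly_order = poly_order))
  } else if (is.matrix(illumination)) {
    illumination <- setNames(rep(list(illumination), length(nms)), nms)
  }
  if (!all(nms %in% names(illumination)))
    gk_stop(sprintf("no illumination field for channel(s): %s",
                    paste(setdiff(nms, names(illumination)), collapse = ", ")))
  af <- autofluorescence
  af_for <- function(nm) {
    if (is.matrix(af)) return(af)
    if (length(af) == 1L && is.null(names(af))) return(af)
    if (!nm %in% names(af))
      gk_stop(sprintf("no autofluorescence value for channel %s", nm))
    af[[nm]]
  }
  out <- fi
  coeffs <- list()
  for (nm in nms) {
    fld <- illumination[[nm]]
    if (any(fld <= 0)) gk_stop("illumination field must be strictly positive")
    out$channels[[nm]] <- pmax(fi$channels[[nm]] / fld - af_for(nm), 0)
    coeffs[[nm]] <- attr(fld, "coeffs")
  }
  out$metadata$correction <- list(poly_order = poly_order,
                                  autofluorescence = autofluorescence,
                                  coeffs = coeffs)
  out
}

#' Estimate a scalar autofluorescence level
#'
#' Median intensity of within-cell pixels after excluding the brightest
#' tail (candidate granule pixels), an estimator for the additive
#' background when no untransfected control region is available.
#'
#' @param image intensity matrix (flat-fielded).
#' @param cell_mask label matrix; pixels > 0 are used.
#' @param exclude_quantile upper quantile treated as granule signal.
#' @return scalar estimate.
#' @export
estimate_autofluorescence <- function(image, cell_mask,
                                      exclude_quantile = 0.9) {
  px <- image[cell_mask > 0]
  if (!length(px)) gk_stop("empty cell mask")
  median(px[px <= quantile(px, exclude_quantile)])
}
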