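# Independent oracles used across the suite.  These deliberately use
# naive, exhaustive, or closed-form routes so they stay independent of
# the implementation paths they check.

# exhaustive Otsu: scan every candidate level, recompute class stats
# from scratch
otsu_bruteforce <- function(x) {
  lv <- sort(unique(x))
  best_v <- -Inf
  best_t <- NA
  for (t in lv[-length(lv)]) {
    lo <- x[x <= t]; hi <- x[x > t]
    w0 <- length(lo) / length(x)
    v <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

# 8-connected labeling by BFS flood fill
label_bruteforce <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!mask[i, j] || lab[i, j]) next
    nxt <- nxt + 1L
    queue <- list(c(i, j))
    lab[i, j] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ni <- p[1] + di; nj <- p[2] + dj
        if (ni < 1 || ni > h || nj < 1 || nj > w) next
        if (mask[ni, nj] && !lab[ni, nj]) {
          lab[ni, nj] <- nxt
          queue[[length(queue) + 1L]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}

# exhaustive optimal one-to-one matching under a distance cutoff:
# maximize the number of matches, then minimize total distance.  Scans
# all permutations (feasible for n <= 6).
match_bruteforce <- function(d, cutoff) {
  nA <- nrow(d); nB <- ncol(d)
  n <- max(nA, nB)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- list(count = -1L, total = Inf, pairs = NULL)
  for (p in perms(seq_len(nB))) {
    pairs <- list(); total <- 0
    for (a in seq_len(min(nA, nB))) {
      b <- p[a]
      if (a <= nA && d[a, b] <= cutoff) {
        pairs[[length(pairs) + 1L]] <- c(a, b)
        total <- total + d[a, b]
      }
    }
    cnt <- length(pairs)
    if (cnt > best$count || (cnt == best$count && total < best$total - 1e-12))
      best <- list(count = cnt, total = total, pairs = pairs)
  }
  best
}

# minimal granule_set for matching tests (no image behind it)
make_gset <- function(rows, cols, cell_id = 1L, pixel_size = 0.1,
                      image_id = "img1", channel = "A") {
  n <- length(rows)
  cell_id <- rep(cell_id, length.out = n)
  df <- data.frame(granule_id = seq_len(n), cell_id = cell_id,
                   row_px = rows, col_px = cols, area_px2 = rep(1, n),
                   eq_diam_um = rep(2 * sqrt(1 / pi) * pixel_size, n),
                   mean_intensity = rep(1, n))
  counts <- table(df$cell_id)
  structure(df, pixel_sets = as.list(seq_len(n)), gate = c(0, Inf),
            threshold = NA_real_, channel = channel, image_id = image_id,
            pixel_size = pixel_size,
            cell_granule_counts = stats::setNames(as.integer(counts),
                                                  names(counts)),
            dim_px = c(100L, 100L),
            class = c("granule_set", "data.frame"))
}

# detection scoring against planted ground truth with 1-px centroid
# matching (one-to-one, nearest first)
score_detection <- function(truth, detected, tol_px = 1) {
  if (!nrow(truth) || !nrow(detected))
    return(list(recall = 0, precision = 0, n_true = nrow(truth),
                n_det = nrow(detected)))
  d <- sqrt(outer(truth$row_px, detected$row_px, `-`)^2 +
            outer(truth$col_px, detected$col_px, `-`)^2)
  used <- rep(FALSE, ncol(d))
  hits <- 0L
  for (i in order(apply(d, 1, min))) {
    j <- which.min(ifelse(used, Inf, d[i, ]))
    if (is.finite(d[i, j]) && d[i, j] <= tol_px && !used[j]) {
      used[j] <- TRUE
      hits <- hits + 1L
    }
  }
  list(recall = hits / nrow(truth), precision = hits / nrow(detected),
       n_true = nrow(truth), n_det = nrow(detected))
}

# draw a disk of given equivalent diameter (um) as foreground pixels on
# a blank image; used for exact gate tests
draw_disk <- function(img, cy, cx, diam_um, pixel_size, value) {
  r <- diam_um / 2 / pixel_size
  h <- nrow(img); w <- ncol(img)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if ((i - cy)^2 + (j - cx)^2 <= r^2) img[i, j] <- value
  }
  img
}
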