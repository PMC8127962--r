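#' Construct a FRAP trace
#'
#' One bleached granule's intensity time course with the first
#' post-bleach frame marked, plus an optional unbleached reference
#' trace for acquisition-bleaching correction.
#'
#' @param times timepoints in seconds, strictly increasing.
#' @param intensities intensities (a.u.), same length as `times`.
#' @param bleach_index index of the first post-bleach frame (>= 2, so
#'   the pre-bleach segment is non-empty).
#' @param reference optional reference-region intensities.
#' @return an object of class `frap_trace`.
#' @export
frap_trace <- function(times, intensities, bleach_index, reference = NULL) {
  if (length(times) != length(intensities))
    gk_stop("`times` and `intensities` must have equal length")
  if (any(diff(times) <= 0)) gk_stop("`times` must be strictly increasing")
  bleach_index <- as.integer(bleach_index)
  if (bleach_index < 2L || bleach_index > length(times))
    gk_stop("`bleach_index` must leave a non-empty pre-bleach segment")
  if (!is.null(reference) && length(reference) != length(times))
    gk_stop("`reference` must match the trace length")
  structure(list(times = as.numeric(times),
                 intensities = as.numeric(intensities),
                 bleach_index = bleach_index, reference = reference,
                 normalized = FALSE),
            class = "frap_trace")
}

#' @export
print.frap_trace <- function(x, ...) {
  cat(sprintf("<frap_trace> %d frames (%d pre-bleach), t = %.1f..%.1f s%s\n",
              length(x$times), x$bleach_index - 1L, min(x$times),
              max(x$times), if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Normalize a FRAP trace
#'
#' Full-scale normalization `F_norm(t) = (F(t) - F_b) / (F_pre - F_b)`
#' with `F_pre` the pre-bleach mean and `F_b` the intensity at the
#' first post-bleach frame, so the pre-bleach level maps to 1 and the
#' bleach frame to 0.  With `acquisition_bleach_correction = TRUE` and a
#' reference trace present, the trace is first divided by the reference
#' scaled to its own pre-bleach mean.  Normalizing an already-normalized
#' trace is the identity.
#'
#' @param trace a [frap_trace()].
#' @param acquisition_bleach_correction logical.
#' @return the normalized `frap_trace` (dimensionless intensities).
#' @examples
#' tr <- frap_trace(0:4 * 3, c(100, 100, 20, 24, 28), bleach_index = 3)
#' normalize_trace(tr)$intensities
#' @export
normalize_trace <- function(trace, acquisition_bleach_correction = FALSE) {
  stopifnot(inherits(trace, "frap_trace"))
  f <- trace$intensities
  if (acquisition_bleach_correction) {
    if (is.null(trace$reference))
      gk_stop("no reference trace for acquisition-bleaching correction")
    pre_ref <- mean(trace$reference[seq_len(trace$bleach_index - 1L)])
    if (pre_ref <= 0) gk_stop("non-positive reference pre-bleach mean")
    f <- f / (trace$reference / pre_ref)
  }
  f_pre <- mean(f[seq_len(trace$bleach_index - 1L)])
  f_b <- f[trace$bleach_index]
  if (f_pre <= f_b) gk_stop("no bleach detected")
  out <- trace
  out$intensities <- (f - f_b) / (f_pre - f_b)
  out$reference <- NULL
  out$normalized <- TRUE
  out
}

#' Mobile fraction as percent recovery at a reference time
#'
#' Reads the normalized trace at the frame nearest `eval_time` seconds
#' after the bleach frame (ties resolved to the earlier frame) and
#' reports it as a percentage.  The default evaluation time is 60 s
#' (percent recovery at 1 min).
#'
#' @param trace a normalized [frap_trace()] (raw traces are normalized
#'   on the fly).
#' @param eval_time seconds after the bleach frame.
#' @param interpolate logical; linearly interpolate between frames
#'   instead of taking the nearest frame.
#' @return percent recovery (one number).
#' @examples
#' tr <- synth_frap_trace(M = 0.4, k = 0.05, noise_sd = 0, seed = 1)
#' mobile_fraction(normalize_trace(tr))  # ~ 100 * 0.4 * (1 - exp(-3))
#' @export
mobile_fraction <- function(trace, eval_time = 60, interpolate = FALSE) {
  stopifnot(inherits(trace, "frap_trace"))
  if (!trace$normalized) trace <- normalize_trace(trace)
  tau <- trace$times - trace$times[trace$bleach_index]
  post <- which(tau >= 0)
  if (max(tau) < eval_time)
    gk_stop(sprintf("trace ends %.1f s after bleach, before eval_time %.1f s",
                    max(tau), eval_time))
  if (interpolate) {
    val <- stats::approx(tau[post], trace$intensities[post],
                         xout = eval_time)$y
  } else {
    d <- abs(tau[post] - eval_time)
    val <- trace$intensities[post[which.min(d)]]  # first = earlier on tie
  }
  100 * val
}

#' Summarize mobile fractions over a population of granules
#'
#' Per-granule percent recovery with the median and range, the
#' population summary used for heterogeneous granule populations.
#'
#' @param traces list of [frap_trace()] objects.
#' @param eval_time seconds after bleach.
#' @return list with `per_granule` (percent per trace), `median`,
#'   `range`, `n`.
#' @export
mobile_fraction_population <- function(traces, eval_time = 60) {
  vals <- vapply(traces, mobile_fraction, numeric(1), eval_time = eval_time)
  list(per_granule = vals, median = median(vals), range = range(vals),
       n = length(vals))
}

#' Fit a single-exponential recovery model
#'
#' Least-squares fit of `M * (1 - exp(-k * t))` to the post-bleach
#' segment of a normalized trace, with `M` constrained to \[0, 1.2\]
#' and `k > 0`.  A bounded `nls` (port algorithm) is tried first; on
#' failure a grid-refined 1-D profile over `k` (with the conditionally
#' optimal `M`) supplies the estimate, flagged as non-converged if the
#' residual norm is large.
#'
#' @param trace normalized [frap_trace()] with >= 5 post-bleach frames.
#' @return list with `M`, `k`, `se_M`, `se_k` (NA when unavailable),
#'   `converged`, `residual_norm`, `k_identifiable`.
#' @examples
#' tr <- synth_frap_trace(M = 0.5, k = 0.1, noise_sd = 0, seed = 1)
#' fit_exponential_recovery(normalize_trace(tr))[c("M", "k")]
#' @export
fit_exponential_recovery <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  if (!trace$normalized) trace <- normalize_trace(trace)
  tau <- trace$times - trace$times[trace$bleach_index]
  post <- tau >= 0
  t <- tau[post]; y <- trace$intensities[post]
  if (length(t) < 5L) gk_stop("need >= 5 post-bleach frames to fit")
  # conditionally optimal M for fixed k (linear in M)
  m_of_k <- function(k) {
    b <- 1 - exp(-k * t)
    denom <- sum(b^2)
    if (denom == 0) return(0)
    min(max(sum(b * y) / denom, 0), 1.2)
  }
  rss <- function(k) {
    m <- m_of_k(k)
    sum((y - m * (1 - exp(-k * t)))^2)
  }
  if (all(abs(y) < 1e-12)) {
    return(list(M = 0, k = NA_real_, se_M = 0, se_k = NA_real_,
                converged = TRUE, residual_norm = 0,
                k_identifiable = FALSE))
  }
  # rates slower than the reciprocal observation window leave M and k
  # jointly unidentifiable (the model degenerates to a line M*k*t); the
  # fit is bounded there and flagged via k_identifiable
  k_min <- 1 / max(t)
  k_grid <- exp(seq(log(k_min), log(10), length.out = 60))
  k0 <- k_grid[which.min(vapply(k_grid, rss, numeric(1)))]
  fit <- tryCatch(
    nls(y ~ M * (1 - exp(-k * t)),
        start = list(M = m_of_k(k0), k = k0),
        lower = c(M = 0, k = k_min), upper = c(M = 1.2, k = Inf),
        algorithm = "port",
        control = list(warnOnly = TRUE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- coef(fit)
    se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
      c(NA_real_, NA_real_))
    res <- sqrt(sum(stats::resid(fit)^2))
    conv <- isTRUE(fit$convInfo$isConv) || fit$convInfo$stopCode %in% 0:4
    return(list(M = unname(cf["M"]), k = unname(cf["k"]),
                se_M = unname(se[1]), se_k = unname(se[2]),
                converged = conv, residual_norm = res,
                k_identifiable = unname(cf["M"]) > 1e-6 &&
                  unname(cf["k"]) > k_min * 1.001))
  }
  opt <- optimize(rss, interval = c(k_min, 10))
  k_hat <- opt$minimum
  list(M = m_of_k(k_hat), k = k_hat, se_M = NA_real_, se_k = NA_real_,
       converged = FALSE, residual_norm = sqrt(opt$objective),
       k_identifiable = m_of_k(k_hat) > 1e-6 && k_hat > k_min * 1.001)
}

#' Read / write FRAP trace CSVs
#'
#' CSV columns: `t_s`, `intensity`, `is_prebleach` (logical/0-1), and
#' optionally `reference`.
#'
#' @param path CSV file path.
#' @return [frap_trace()] (read) or `path` invisibly (write).
#' @export
read_frap_csv <- function(path) {
  df <- read.csv(path)
  need <- c("t_s", "intensity", "is_prebleach")
  if (!all(need %in% names(df)))
    gk_stop("FRAP CSV needs columns t_s, intensity, is_prebleach")
  pre <- as.logical(df$is_prebleach)
  frap_trace(df$t_s, df$intensity, bleach_index = sum(pre) + 1L,
             reference = df$reference)
}

#' @rdname read_frap_csv
#' @param trace a [frap_trace()].
#' @export
write_frap_csv <- function(trace, path) {
  stopifnot(inherits(trace, "frap_trace"))
  df <- data.frame(
    t_s = trace$times, intensity = trace$intensities,
    is_prebleach = seq_along(trace$times) < trace$bleach_index)
  if (!is.null(trace$reference)) df$reference <- trace$reference
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
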