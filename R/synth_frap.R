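#' Simulate a FRAP trace from a two-state exchange model
#'
#' Pre-bleach frames sit at 1.0; from the first post-bleach frame the
#' normalized mean follows
#' `bleach_depth + (1 - bleach_depth) * M * (1 - exp(-k * t))`,
#' with `t` measured from the first post-bleach frame and frames spaced
#' `dt` seconds apart, plus Gaussian noise on the post-bleach frames.
#' `M` is the mobile fraction: the proportion of bleached molecules that
#' exchange with the surrounding cytosol.
#'
#' @param M mobile fraction, in \[0, 1\].
#' @param k exchange rate, 1/s (>= 0).
#' @param bleach_depth fraction of pre-bleach intensity remaining at the
#'   first post-bleach frame, in \[0, 1).
#' @param dt frame interval in seconds (default 3 s, a typical confocal
#'   FRAP acquisition interval).
#' @param noise_sd Gaussian noise standard deviation (dimensionless).
#' @param n_pre number of pre-bleach frames (>= 1).
#' @param n_post number of post-bleach frames (>= 2); the default spans
#'   one minute at `dt = 3`.
#' @param seed integer seed.
#' @return a [frap_trace()] carrying the ground truth in
#'   `attr(, "truth")`.
#' @examples
#' tr <- synth_frap_trace(M = 0.4, k = 0.05, seed = 1)
#' mobile_fraction(normalize_trace(tr))
#' @export
synth_frap_trace <- function(M, k, bleach_depth = 0.2, dt = 3,
                             noise_sd = 0.02, n_pre = 5, n_post = 21,
                             seed) {
  if (missing(seed)) gk_stop("`seed` is required for reproducibility")
  gk_check_fraction(M, "M")
  if (k < 0) gk_stop("`k` must be >= 0")
  if (bleach_depth < 0 || bleach_depth >= 1)
    gk_stop("`bleach_depth` must lie in [0, 1)")
  gk_check_positive(dt, "dt")
  if (n_pre < 1) gk_stop("`n_pre` must be >= 1")
  if (n_post < 2) gk_stop("`n_post` must be >= 2")
  set.seed(as.integer(seed))
  times <- seq(0, by = dt, length.out = n_pre + n_post)
  tau <- times[(n_pre + 1):(n_pre + n_post)] - times[n_pre + 1]
  post <- bleach_depth + (1 - bleach_depth) * M * (1 - exp(-k * tau))
  if (noise_sd > 0) post <- post + rnorm(n_post, 0, noise_sd)
  tr <- frap_trace(times = times,
                   intensities = c(rep(1, n_pre), post),
                   bleach_index = n_pre + 1L)
  attr(tr, "truth") <- list(M = M, k = k, bleach_depth = bleach_depth,
                            dt = dt, noise_sd = noise_sd,
                            seed = as.integer(seed))
  tr
}

#' Simulate a densitometry table with known ground truth
#'
#' Band intensities carry multiplicative lognormal noise with unit mean
#' (`exp(rnorm(0, sd) - sd^2/2)`).  Two blocks are generated: a
#' fractionation block (pellet and supernatant bands whose noiseless
#' ratio pellet/(pellet+sup) is `true_pellet_fraction`) and, when
#' `true_ratio_chain` is given, a signaling block with `signal`,
#' `loading`, and `expression` bands for a `sample` and a `control`
#' condition whose planted double-normalized level is
#' `(signal/loading) / expression` relative to control.
#'
#' @param true_pellet_fraction planted insoluble fraction, in \[0, 1\].
#' @param true_ratio_chain optional named numeric vector with elements
#'   `signal`, `loading`, `expression`: sample/control fold for each
#'   band type.
#' @param n_replicates replicates per condition (>= 1).
#' @param lognormal_sd sdlog of the multiplicative noise (0 = noiseless).
#' @param total total (pellet + supernatant) noiseless intensity, a.u.
#' @param seed integer seed.
#' @return a data frame with columns `analyte`, `condition`,
#'   `replicate`, `band_intensity`, plus attribute `truth`.
#' @export
synth_densitometry <- function(true_pellet_fraction = 0.8,
                               true_ratio_chain = NULL,
                               n_replicates = 3, lognormal_sd = 0.1,
                               total = 1000, seed) {
  if (missing(seed)) gk_stop("`seed` is required for reproducibility")
  gk_check_fraction(true_pellet_fraction, "true_pellet_fraction")
  if (n_replicates < 1) gk_stop("`n_replicates` must be >= 1")
  if (lognormal_sd < 0) gk_stop("`lognormal_sd` must be >= 0")
  set.seed(as.integer(seed))
  lnoise <- function(n) {
    if (lognormal_sd == 0) rep(1, n)
    else exp(rnorm(n, -lognormal_sd^2 / 2, lognormal_sd))
  }
  reps <- seq_len(n_replicates)
  rows <- rbind(
    data.frame(analyte = "target", condition = "pellet", replicate = reps,
               band_intensity = true_pellet_fraction * total * lnoise(n_replicates)),
    data.frame(analyte = "target", condition = "supernatant", replicate = reps,
               band_intensity = (1 - true_pellet_fraction) * total *
                 lnoise(n_replicates)))
  if (!is.null(true_ratio_chain)) {
    need <- c("signal", "loading", "expression")
    if (!all(need %in% names(true_ratio_chain)))
      gk_stop("`true_ratio_chain` needs elements signal, loading, expression")
    base <- total / 2
    for (band in need) {
      fold <- true_ratio_chain[[band]]
      rows <- rbind(
        rows,
        data.frame(analyte = band, condition = "control", replicate = reps,
                   band_intensity = base * lnoise(n_replicates)),
        data.frame(analyte = band, condition = "sample", replicate = reps,
                   band_intensity = fold * base * lnoise(n_replicates)))
    }
  }
  attr(rows, "truth") <- list(
    pellet_fraction = true_pellet_fraction,
    ratio_chain = true_ratio_chain,
    planted_level = if (is.null(true_ratio_chain)) NULL else
      (true_ratio_chain[["signal"]] / true_ratio_chain[["loading"]]) /
        true_ratio_chain[["expression"]],
    lognormal_sd = lognormal_sd, seed = as.integer(seed))
  rows
}
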