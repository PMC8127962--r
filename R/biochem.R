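#' Fraction of protein in the insoluble pellet
#'
#' `pellet / (pellet + supernatant)` per replicate, summarized as
#' mean +/- SEM.  The complementary supernatant fraction is returned so
#' the two sum to 1 exactly per replicate.
#'
#' @param pellet,supernatant band intensities (a.u., >= 0), one value
#'   per replicate, equal lengths.
#' @return list with `per_replicate` (replicate, fraction_pellet,
#'   fraction_supernatant), `mean`, `sem`.
#' @examples
#' fraction_in_pellet(75, 25)$per_replicate$fraction_pellet  # 0.75
#' @export
fraction_in_pellet <- function(pellet, supernatant) {
  if (length(pellet) != length(supernatant))
    gk_stop("`pellet` and `supernatant` must have equal length")
  if (any(pellet < 0) || any(supernatant < 0))
    gk_stop("band intensities must be >= 0")
  tot <- pellet + supernatant
  bad <- which(tot == 0)
  if (length(bad))
    gk_stop(sprintf("replicate(s) %s: both bands zero",
                    paste(bad, collapse = ", ")))
  f <- pellet / tot
  list(per_replicate = data.frame(replicate = seq_along(f),
                                  fraction_pellet = f,
                                  fraction_supernatant = 1 - f),
       mean = mean(f),
       sem = if (length(f) >= 2) sem(f) else NA_real_)
}

#' Detergent-shift effect on pellet fraction
#'
#' Paired difference in fraction-in-pellet without versus with
#' detergent, per replicate; membrane-associated proteins shift to the
#' supernatant with detergent while membraneless assemblies do not.
#'
#' @param pellet_minus,sup_minus bands without detergent.
#' @param pellet_plus,sup_plus bands with detergent, paired by position.
#' @return list with `per_replicate` differences, `mean`, `sem`.
#' @export
detergent_shift <- function(pellet_minus, sup_minus, pellet_plus, sup_plus) {
  f0 <- fraction_in_pellet(pellet_minus, sup_minus)$per_replicate$fraction_pellet
  f1 <- fraction_in_pellet(pellet_plus, sup_plus)$per_replicate$fraction_pellet
  if (length(f0) != length(f1)) gk_stop("unpaired replicate counts")
  d <- f0 - f1
  list(per_replicate = data.frame(replicate = seq_along(d), difference = d),
       mean = mean(d), sem = if (length(d) >= 2) sem(d) else NA_real_)
}

#' Double-normalized active-RAS (RAS-GTP) level
#'
#' `((gtp / total) / (gtp_ctrl / total_ctrl)) / (expression /
#' expression_ctrl)`: the pulldown signal is normalized to total RAS,
#' standardized against the control condition, then corrected for the
#' expression level of the fusion oncoprotein.  Omit the expression pair
#' (leave `NULL`) when the comparison is within one construct (e.g.
#' drug +/-), in which case the third factor is 1.  The control
#' normalizes to exactly 1 by construction.
#'
#' @param gtp,total active-RAS and total-RAS band intensities
#'   (vectors over replicates).
#' @param gtp_ctrl,total_ctrl the control condition's bands.
#' @param expression,expression_ctrl optional oncoprotein expression
#'   bands.
#' @param aggregate `"arithmetic"` (mean of per-replicate ratios,
#'   the replicate-mean convention) or `"geometric"` (suited to
#'   lognormal band noise).
#' @return list with `per_replicate` normalized levels, `mean`, `sem`.
#' @examples
#' normalize_ras_gtp(200, 100, 100, 100)$mean  # 2
#' @export
normalize_ras_gtp <- function(gtp, total, gtp_ctrl, total_ctrl,
                              expression = NULL, expression_ctrl = NULL,
                              aggregate = c("arithmetic", "geometric")) {
  normalize_band_ratio(signal = gtp, loading = total,
                       signal_ctrl = gtp_ctrl, loading_ctrl = total_ctrl,
                       expression = expression,
                       expression_ctrl = expression_ctrl,
                       aggregate = aggregate)
}

#' Double-normalized band ratio (e.g. pERK / total ERK)
#'
#' General engine behind [normalize_ras_gtp()]: a phospho/total (or any
#' signal/loading) ratio standardized to a control condition and
#' optionally corrected for construct expression level.
#'
#' @param signal,loading band intensities over replicates.
#' @param signal_ctrl,loading_ctrl control condition bands.
#' @param expression,expression_ctrl optional expression bands.
#' @param aggregate see [normalize_ras_gtp()].
#' @return list with `per_replicate`, `mean`, `sem`.
#' @export
normalize_band_ratio <- function(signal, loading, signal_ctrl, loading_ctrl,
                                 expression = NULL, expression_ctrl = NULL,
                                 aggregate = c("arithmetic", "geometric")) {
  aggregate <- match.arg(aggregate)
  check_pos <- function(x, nm) {
    if (any(!is.finite(x)) || any(x <= 0))
      gk_stop(sprintf("zero or invalid denominator band: %s", nm))
  }
  if (any(signal < 0) || any(signal_ctrl < 0))
    gk_stop("band intensities must be >= 0")
  check_pos(loading, "loading")
  check_pos(loading_ctrl, "loading_ctrl")
  ratio <- signal / loading
  ratio_ctrl <- signal_ctrl / loading_ctrl
  check_pos(ratio_ctrl, "control signal/loading ratio")
  # replicate-wise standardization when lengths agree, else against the
  # control's aggregate
  ctrl_ref <- if (length(ratio_ctrl) == length(ratio)) ratio_ctrl
              else mean(ratio_ctrl)
  lev <- ratio / ctrl_ref
  if (!is.null(expression)) {
    if (is.null(expression_ctrl))
      gk_stop("`expression_ctrl` required with `expression`")
    check_pos(expression, "expression")
    check_pos(expression_ctrl, "expression_ctrl")
    expr_ref <- if (length(expression_ctrl) == length(expression))
      expression_ctrl else mean(expression_ctrl)
    lev <- lev / (expression / expr_ref)
  }
  mu <- if (aggregate == "arithmetic") mean(lev) else exp(mean(log(lev)))
  list(per_replicate = data.frame(replicate = seq_along(lev),
                                  level = lev),
       mean = mu, sem = if (length(lev) >= 2) sem(lev) else NA_real_,
       aggregate = aggregate)
}

#' Compute pellet fractions from a densitometry table
#'
#' Convenience wrapper taking the long table produced by
#' [synth_densitometry()] (or read from CSV): columns `analyte`,
#' `condition` (with `pellet` / `supernatant` rows), `replicate`,
#' `band_intensity`.
#'
#' @param tab densitometry data frame.
#' @param analyte which analyte to quantify (default first).
#' @return as [fraction_in_pellet()].
#' @export
pellet_fraction_from_table <- function(tab, analyte = NULL) {
  if (is.null(analyte)) analyte <- tab$analyte[1]
  sub <- tab[tab$analyte == analyte, ]
  p <- sub[sub$condition == "pellet", ]
  s <- sub[sub$condition == "supernatant", ]
  p <- p[order(p$replicate), ]; s <- s[order(s$replicate), ]
  if (!nrow(p) || !identical(p$replicate, s$replicate))
    gk_stop("table lacks paired pellet/supernatant rows")
  fraction_in_pellet(p$band_intensity, s$band_intensity)
}
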