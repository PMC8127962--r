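#' Standard error of the mean
#'
#' Sample standard deviation (n - 1 denominator) divided by `sqrt(n)`,
#' the convention behind "+/- SEM" error bars.
#'
#' @param values numeric vector with n >= 2.
#' @return the SEM.
#' @examples
#' sem(c(0, 2))  # 1
#' @export
sem <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L) gk_stop("SEM needs n >= 2")
  sd(values) / sqrt(n)
}

#' Student's t test (unpaired pooled-variance or paired)
#'
#' The classic equal-variance statistic for two independent samples, or
#' the difference-based statistic for paired samples; two-sided p from
#' the t distribution.  A Welch option relaxes the equal-variance
#' assumption.  When the pooled variance is zero with equal means, the
#' comparison is degenerate: t = 0, p = 1, flagged.
#'
#' @param a,b numeric vectors, n >= 2 each; equal lengths when paired.
#' @param paired logical.
#' @param welch logical; Welch-Satterthwaite correction (unpaired only).
#' @return list with `t`, `df`, `p`, `mean_a`, `mean_b`, `paired`,
#'   `degenerate`.
#' @examples
#' t_test(c(1, 2, 3), c(1, 2, 3))$p  # 1
#' @export
t_test <- function(a, b, paired = FALSE, welch = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) gk_stop("need n >= 2 per sample")
  if (paired) {
    if (length(a) != length(b))
      gk_stop("paired test requires equal sample sizes")
    d <- a - b
    n <- length(d)
    v <- var(d)
    if (v == 0) {
      if (mean(d) == 0)
        return(list(t = 0, df = n - 1, p = 1, mean_a = mean(a),
                    mean_b = mean(b), paired = TRUE, degenerate = TRUE))
      gk_stop("zero variance of differences with nonzero mean difference")
    }
    tstat <- mean(d) / sqrt(v / n)
    df <- n - 1
  } else {
    na <- length(a); nb <- length(b)
    va <- var(a); vb <- var(b)
    if (welch) {
      se2 <- va / na + vb / nb
      if (se2 == 0) {
        return(list(t = 0, df = na + nb - 2, p = 1, mean_a = mean(a),
                    mean_b = mean(b), paired = FALSE, degenerate = TRUE))
      }
      tstat <- (mean(a) - mean(b)) / sqrt(se2)
      df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    } else {
      sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
      df <- na + nb - 2
      if (sp2 == 0) {
        if (mean(a) == mean(b))
          return(list(t = 0, df = df, p = 1, mean_a = mean(a),
                      mean_b = mean(b), paired = FALSE, degenerate = TRUE))
        gk_stop("zero pooled variance with unequal means")
      }
      tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    }
  }
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df),
       mean_a = mean(a), mean_b = mean(b), paired = paired,
       degenerate = FALSE)
}

#' One-way ANOVA with post hoc Tukey HSD
#'
#' Classic one-way ANOVA (F and p) followed by all pairwise Tukey HSD
#' comparisons: `q = |mean_i - mean_j| / sqrt(MSE * (1/n_i + 1/n_j) / 2)`
#' with adjusted p from the studentized-range distribution
#' (Tukey-Kramer for unequal group sizes).  The studentized-range CDF
#' is evaluated by numerical integration (`stats::ptukey`); the test
#' suite cross-checks it against a Monte-Carlo null.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each
#'   n >= 2), or a data frame with columns `value` and `group`.
#' @param alpha familywise significance level for the `significant`
#'   column.
#' @return list with `F`, `df`, `p_overall`, `pairwise` (data frame:
#'   group_i, group_j, diff, q, p_adj, significant), `mse`,
#'   `group_means`, `group_n`.
#' @examples
#' g <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(8, 9, 10))
#' anova_tukey(g)$pairwise
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  if (is.data.frame(groups)) {
    if (!all(c("value", "group") %in% names(groups)))
      gk_stop("data frame input needs columns `value` and `group`")
    groups <- split(groups$value, groups$group)
  }
  k <- length(groups)
  if (k < 2L) gk_stop("need >= 2 groups")
  n <- vapply(groups, length, integer(1))
  if (any(n < 2L)) gk_stop("each group needs n >= 2")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  m <- vapply(groups, mean, numeric(1))
  N <- sum(n)
  grand <- sum(n * m) / N
  ss_between <- sum(n * (m - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  df1 <- k - 1; df2 <- N - k
  mse <- ss_within / df2
  if (mse == 0 && ss_between == 0) {
    Fstat <- 0; p_overall <- 1
  } else if (mse == 0) {
    Fstat <- Inf; p_overall <- 0
  } else {
    Fstat <- (ss_between / df1) / mse
    p_overall <- pf(Fstat, df1, df2, lower.tail = FALSE)
  }
  ij <- utils::combn(k, 2)
  pw <- data.frame(group_i = names(groups)[ij[1, ]],
                   group_j = names(groups)[ij[2, ]])
  pw$diff <- m[ij[2, ]] - m[ij[1, ]]
  se <- sqrt(mse * (1 / n[ij[1, ]] + 1 / n[ij[2, ]]) / 2)
  pw$q <- ifelse(se == 0, ifelse(pw$diff == 0, 0, Inf), abs(pw$diff) / se)
  pw$p_adj <- ifelse(is.infinite(pw$q), 0,
                     ptukey(pw$q, nmeans = k, df = df2, lower.tail = FALSE))
  pw$p_adj[pw$q == 0] <- 1
  pw$significant <- pw$p_adj < alpha
  rownames(pw) <- NULL
  list(F = Fstat, df = c(df1, df2), p_overall = p_overall, pairwise = pw,
       mse = mse, group_means = m, group_n = n, alpha = alpha)
}

#' Significance stars for p values
#'
#' Figure-legend convention: `*` p < 0.05, `**` p < 0.01, `***`
#' p < 0.001, `n.s.` otherwise.
#'
#' @param p numeric vector of p values.
#' @return character vector.
#' @export
p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
    ifelse(p < 0.05, "*", "n.s.")))
}
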