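#' Mann-Whitney U test
#'
#' Rank-sum test of two independent samples.  For combined sample sizes of
#' at most 20 with no ties the two-sided p-value is exact (enumeration of
#' the U null distribution); otherwise a normal approximation with tie
#' correction is used (no continuity correction).
#'
#' @param x,y Non-empty numeric samples; ties allowed.
#' @return list: `U` (statistic for `x`), `p` (two-sided), `method`.
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop_famprs("both samples must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (n1 + n2 <= 20 && !ties) {
    # exact: P(U <= min(U, n1n2-U)) doubled, capped at 1
    p <- min(1, 2 * pwilcox(min(U, n1 * n2 - U), n1, n2))
    method <- "exact"
  } else {
    tt <- table(r)
    mu <- n1 * n2 / 2
    sig2 <- n1 * n2 / 12 *
      ((n1 + n2 + 1) - sum(tt^3 - tt) / ((n1 + n2) * (n1 + n2 - 1)))
    z <- if (sig2 > 0) (U - mu) / sqrt(sig2) else 0
    p <- 2 * pnorm(-abs(z))
    method <- "normal_tie_corrected"
  }
  list(U = U, p = p, method = method)
}

#' Pearson chi-squared test on a contingency table
#'
#' No continuity correction; degrees of freedom `(r-1)(c-1)` unless
#' overridden.
#'
#' @param tab Matrix of counts.
#' @param df Optional degrees of freedom.
#' @return list: `statistic`, `df`, `p`.
#' @export
chi_squared <- function(tab, df = NULL) {
  tab <- as.matrix(tab)
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0))
    stop_famprs("zero marginal in contingency table")
  expected <- outer(rs, cs) / n
  stat <- sum((tab - expected)^2 / expected)
  df <- df %||% ((nrow(tab) - 1) * (ncol(tab) - 1))
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

#' Percentage of a group, half-up rounded to one decimal
#'
#' @param n_sub Numerator count (0 <= n_sub <= n_group).
#' @param n_group Group size (> 0).
#' @return `100 * n_sub / n_group` rounded half-up to 1 dp.
#' @export
percent_summary <- function(n_sub, n_group) {
  if (n_group <= 0) stop_famprs("n_group must be positive")
  if (n_sub < 0 || n_sub > n_group)
    stop_famprs("need 0 <= n_sub <= n_group")
  half_up(100 * n_sub / n_group, 1)
}

#' Median and (unscaled) median absolute deviation
#'
#' MAD without the 1.4826 normal-consistency constant, matching
#' raw-descriptive reporting.  Missing values are excluded and counted.
#'
#' @param x Numeric sample with at least one non-missing value.
#' @return list: `median`, `mad`, `n`, `missing`.
#' @export
median_mad <- function(x) {
  miss <- sum(is.na(x))
  x <- x[!is.na(x)]
  if (!length(x)) stop_famprs("all values missing")
  m <- median(x)
  list(median = m, mad = median(abs(x - m)), n = length(x), missing = miss)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise level in (0,1).
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni <- function(alpha, m) {
  if (m < 1) stop_famprs("m must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop_famprs("alpha must lie in (0,1)")
  alpha / m
}
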