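#' LD score regression: SNP heritability
#'
#' Weighted least-squares fit of per-variant association chi-square on LD
#' scores, `chi2_j = intercept + (N h2 / M) l_j`, with default weights
#' `1 / max(l_j, 1)`.  The slope yields the heritability estimate; the
#' intercept (1 under no confounding) is reported alongside.
#'
#' @param stats A `summary_stats` with BETA and SE (z = BETA/SE).
#' @param ld_scores data.frame with columns `SNP`, `L2`.
#' @param N GWAS sample size (defaults to the median of the N column).
#' @param M Number of variants the heritability is defined over
#'   (defaults to the number of regression variants).
#' @param fixed_intercept Constrain the intercept to its no-confounding
#'   value (1 for chi-square, 0 for z-score products); needed when LD
#'   scores have little spread, e.g. linkage-equilibrium simulations.
#' @return list of class `ldsc_estimate`: `h2`, `intercept`, `M`, `n_snps`.
#' @export
ldsc_h2 <- function(stats, ld_scores, N = NULL, M = NULL,
                    fixed_intercept = FALSE) {
  i <- match(stats$SNP, ld_scores$SNP)
  ok <- !is.na(i) & !is.na(stats$BETA) & !is.na(stats$SE) & stats$SE > 0
  if (sum(ok) < 10)
    stop_famprs("ldsc_h2 needs at least 10 variants with LD scores")
  l <- ld_scores$L2[i[ok]]
  chi2 <- (stats$BETA[ok] / stats$SE[ok])^2
  N <- N %||% median(stats$N[ok], na.rm = TRUE)
  M <- M %||% sum(ok)
  fit <- if (fixed_intercept) wls_fit0(chi2 - 1, l, 1 / pmax(l, 1))
  else wls_fit(chi2, l, 1 / pmax(l, 1))
  if (fixed_intercept) fit$intercept <- 1
  structure(list(h2 = fit$slope * M / N, intercept = fit$intercept,
                 M = M, n_snps = sum(ok)),
            class = "ldsc_estimate")
}

#' LD score regression: coheritability and genetic correlation
#'
#' Bivariate fit of per-variant z-score products on LD scores,
#' `z1_j z2_j = intercept + (sqrt(N1 N2) rho_g / M) l_j`, after orienting
#' the second study to the first study's effect alleles.  The genetic
#' correlation `r_g = rho_g / sqrt(h2_1 h2_2)` is derived from univariate
#' [ldsc_h2()] fits of each input and clamped to [-1, 1].
#'
#' @param stats1,stats2 `summary_stats` for the two traits.
#' @param ld_scores data.frame `SNP`, `L2`.
#' @param N1,N2 Sample sizes (defaults as in [ldsc_h2()]).
#' @param M Variant count for the definition of rho_g.
#' @inheritParams ldsc_h2
#' @return list of class `ldsc_estimate`: `rho_g`, `rg`, `h2_1`, `h2_2`,
#'   `intercept`, `M`, `n_snps`.
#' @export
ldsc_coherit <- function(stats1, stats2, ld_scores, N1 = NULL, N2 = NULL,
                         M = NULL, fixed_intercept = FALSE) {
  stats2 <- orient_to_reference(stats1, stats2)
  ids <- intersect(stats1$SNP, stats2$SNP)
  if (length(ids) < 10)
    stop_famprs("ldsc_coherit needs at least 10 shared variants")
  i1 <- match(ids, stats1$SNP); i2 <- match(ids, stats2$SNP)
  il <- match(ids, ld_scores$SNP)
  ok <- !is.na(il)
  z1 <- stats1$BETA[i1][ok] / stats1$SE[i1][ok]
  z2 <- stats2$BETA[i2][ok] / stats2$SE[i2][ok]
  l <- ld_scores$L2[il[ok]]
  N1 <- N1 %||% median(stats1$N[i1], na.rm = TRUE)
  N2 <- N2 %||% median(stats2$N[i2], na.rm = TRUE)
  M <- M %||% sum(ok)
  fit <- if (fixed_intercept) wls_fit0(z1 * z2, l, 1 / pmax(l, 1))
  else wls_fit(z1 * z2, l, 1 / pmax(l, 1))
  if (fixed_intercept) fit$intercept <- 0
  rho_g <- fit$slope * M / sqrt(N1 * N2)
  h1 <- ldsc_h2(stats1, ld_scores, N = N1, M = M,
                fixed_intercept = fixed_intercept)
  h2 <- ldsc_h2(stats2, ld_scores, N = N2, M = M,
                fixed_intercept = fixed_intercept)
  rg <- if (h1$h2 > 0 && h2$h2 > 0)
    max(-1, min(1, rho_g / sqrt(h1$h2 * h2$h2))) else NA_real_
  structure(list(rho_g = rho_g, rg = rg, h2_1 = h1$h2, h2_2 = h2$h2,
                 intercept = fit$intercept, M = M, n_snps = sum(ok)),
            class = "ldsc_estimate")
}

#' @export
print.ldsc_estimate <- function(x, ...) {
  cat("LDSC estimate:")
  if (!is.null(x$h2)) cat(" h2 =", signif(x$h2, 4))
  if (!is.null(x$rho_g)) cat(" rho_g =", signif(x$rho_g, 4),
                             " rg =", signif(x$rg, 4))
  cat(", intercept =", signif(x$intercept, 4), ", M =", x$M, "\n")
  invisible(x)
}

# weighted regression through the origin
wls_fit0 <- function(y, x, w) {
  list(slope = sum(w * x * y) / sum(w * x^2), intercept = 0)
}

# one-predictor weighted least squares, returns slope + intercept
wls_fit <- function(y, x, w) {
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  slope <- sum(w * (x - mx) * (y - my)) / sum(w * (x - mx)^2)
  list(slope = slope, intercept = my - slope * mx)
}

#' Empirical LD scores from a dosage panel
#'
#' `l_j = sum_k r^2_jk` over all variants k within `window` positions of j
#' (including j itself), with r the Pearson dosage correlation.
#'
#' @param panel A `dosage_panel`.
#' @param window One-sided window in variant index units.
#' @return data.frame `SNP`, `L2`.
#' @export
compute_ld_scores <- function(panel, window = 50L) {
  D <- panel$dosage
  m <- ncol(D)
  sds <- apply(D, 2, sd)
  l <- numeric(m)
  Z <- scale(D)
  for (j in seq_len(m)) {
    if (sds[j] == 0) { l[j] <- NA_real_; next }
    lo <- max(1L, j - window); hi <- min(m, j + window)
    idx <- lo:hi
    idx <- idx[sds[idx] > 0]
    r <- crossprod(Z[, j], Z[, idx, drop = FALSE]) / (nrow(D) - 1)
    l[j] <- sum(r^2)
  }
  data.frame(SNP = panel$variants$variant_id, L2 = l)
}
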