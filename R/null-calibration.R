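#' Simulated-PRS null ensemble
#'
#' Draws `n_sim` random scores per p-value threshold: at each threshold the
#' same number of variants as the observed BD PRS is sampled uniformly
#' without replacement from the panel, and weights are sampled with
#' replacement from the pooled harmonised effects of all disorder GWAS.
#' Scores are computed with [prs_score()] and Z-standardised.  Thresholds
#' whose BD SNP count is zero are skipped and logged.
#'
#' @param panel A `dosage_panel` restricted to the analysis subjects.
#' @param bd_counts Named (by threshold) integer vector of BD PRS SNP
#'   counts per threshold.
#' @param effect_pool Numeric vector of harmonised (non-negative) effects.
#' @param n_sim Number of simulated scores per threshold.
#' @param seed Integer seed.
#' @return list of class `null_prs_ensemble`: `scores` (named list of
#'   subjects x n_sim matrices of standardised scores), `skipped`,
#'   `n_sim`, `seed`.
#' @export
draw_null_prs <- function(panel, bd_counts, effect_pool, n_sim = 10000L,
                          seed = 1L) {
  if (!length(effect_pool)) stop_famprs("empty effect pool")
  if (any(effect_pool < 0))
    stop_famprs("effect pool must be positively harmonised")
  m <- ncol(panel$dosage)
  if (max(bd_counts) > m)
    stop_famprs("BD SNP count exceeds panel size")
  scores <- list(); skipped <- character(0)
  with_substream(seed, "null_prs", {
    for (thr in names(bd_counts)) {
      cnt <- bd_counts[[thr]]
      if (cnt == 0) {
        skipped <- c(skipped, thr)
        next
      }
      S <- matrix(NA_real_, nrow(panel$dosage), n_sim)
      D <- panel$dosage
      for (s in seq_len(n_sim)) {
        j <- sample.int(m, cnt)
        w <- effect_pool[sample.int(length(effect_pool), cnt,
                                    replace = TRUE)]
        raw <- as.numeric(D[, j, drop = FALSE] %*% w)
        S[, s] <- if (sd(raw) > 0) zstandardize(raw) else 0
      }
      rownames(S) <- rownames(panel$dosage)
      scores[[thr]] <- S
    }
  })
  if (length(skipped))
    message("null ensemble: skipped threshold(s) with 0 BD SNPs: ",
            paste(skipped, collapse = ", "))
  structure(list(scores = scores, skipped = skipped, n_sim = n_sim,
                 seed = seed),
            class = "null_prs_ensemble")
}

#' Fast association scan of an ensemble (AI-REML style fixed-V path)
#'
#' For the 10,000 x 10 null fits the full logistic mixed model is replaced
#' by the linear-mixed-model approximation: variance components are
#' estimated once by REML on the outcome without the score, the resulting
#' covariance is fixed, and every simulated score gets a GLS Wald test.
#' One-sided p-values follow the same "group 1 higher" convention as
#' [fit_logistic_mixed()].
#'
#' @param ensemble A `null_prs_ensemble` (or one scores matrix).
#' @param y Binary (or quantitative) outcome.
#' @param covariates Optional fixed covariates.
#' @param K GRM for the subjects of `y`.
#' @return Matrix `n_sim` x thresholds of one-sided p-values.
#' @export
null_assoc_scan <- function(ensemble, y, covariates = NULL, K) {
  X <- build_design(NULL, covariates, n = length(y))
  base <- reml_fit(y, X, K = K)
  Vi <- chol2inv(base$chol)
  ViX <- Vi %*% X
  P <- Vi - ViX %*% solve(crossprod(X, ViX), t(ViX))
  Py <- P %*% y
  mats <- if (inherits(ensemble, "null_prs_ensemble")) ensemble$scores
  else list(score = ensemble)
  out <- sapply(mats, function(S) {
    num <- crossprod(S, Py)
    den <- colSums(S * (P %*% S))
    zs <- as.numeric(num) / sqrt(den)
    1 - pnorm(zs)
  })
  if (is.null(dim(out))) out <- matrix(out, ncol = length(mats),
                                       dimnames = list(NULL, names(mats)))
  out
}

#' Choose the comparison threshold for the null calibration
#'
#' Returns the threshold (column) with the lowest mean simulated
#' association p-value; exact ties are broken toward the more permissive
#' (larger) threshold with a message.
#'
#' @param sim_p Matrix n_sim x thresholds of p-values, columns named by
#'   threshold.
#' @return The chosen threshold (numeric if column names are numeric).
#' @export
choose_threshold <- function(sim_p) {
  mu <- colMeans(sim_p, na.rm = TRUE)
  mu <- mu[!is.nan(mu)]
  if (!length(mu)) stop_famprs("no threshold with defined p-values")
  best <- which(mu == min(mu))
  thr <- names(mu)[best]
  if (length(best) > 1) {
    thr <- thr[which.max(suppressWarnings(as.numeric(thr)))]
    message("choose_threshold: tie broken toward the larger threshold ", thr)
  }
  out <- suppressWarnings(as.numeric(thr))
  if (is.na(out)) thr else out
}

#' Exact binomial success test (Clopper-Pearson)
#'
#' Estimate `k/n` with the exact 95% CI: lower bound
#' `qbeta(0.025, k, n-k+1)` (0 when k = 0), upper bound
#' `qbeta(0.975, k+1, n-k)` (1 when k = n).  The significance flag
#' compares the estimate against `alpha` (0.05/16 by default, the
#' per-table Bonferroni convention).
#'
#' @param k Successes (0 <= k <= n).
#' @param n Trials (>= 1).
#' @param alpha Significance threshold for the flag.
#' @return list of class `calibration_result`: `k`, `n`, `estimate`, `ci`,
#'   `significant`.
#' @export
binomial_success_test <- function(k, n, alpha = 0.05 / 16) {
  if (n < 1 || k < 0 || k > n) stop_famprs("need 0 <= k <= n, n >= 1")
  lower <- if (k == 0) 0 else qbeta(0.025, k, n - k + 1)
  upper <- if (k == n) 1 else qbeta(0.975, k + 1, n - k)
  structure(list(k = k, n = n, estimate = k / n, ci = c(lower, upper),
                 significant = k / n < alpha),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  est <- if (x$k == 0) "<1e-04" else sprintf("%.4f", half_up(x$estimate, 4))
  cat(sprintf("binomial success test: %d/%d = %s, 95%% CI %.3f-%.3f%s\n",
              x$k, x$n, est, half_up(x$ci[1], 3), half_up(x$ci[2], 3),
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Calibrate a disorder PRS against the simulated null
#'
#' Counts the simulated scores whose one-sided association p-value is at
#' most the disorder PRS's p-value at the same threshold (ties count as
#' successes) and delegates to [binomial_success_test()].
#'
#' @param p_disorder One-sided p of the disorder PRS at the chosen
#'   threshold.
#' @param sim_p Vector of one-sided p-values of the ensemble at that same
#'   threshold.
#' @param alpha Significance threshold for the flag.
#' @return A `calibration_result` with the chosen threshold attached.
#' @export
calibrate_contrast <- function(p_disorder, sim_p, alpha = 0.05 / 16) {
  sim_p <- sim_p[!is.na(sim_p)]
  if (!length(sim_p)) stop_famprs("no simulated p-values at this threshold")
  binomial_success_test(sum(sim_p <= p_disorder), length(sim_p),
                        alpha = alpha)
}
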