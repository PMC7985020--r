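#' Simulate training-GWAS summary statistics
#'
#' Emulates an external case/control GWAS of a configured disorder under
#' linkage equilibrium: the estimated per-allele effect is the true effect
#' plus Gaussian noise with `SE_j = 1 / sqrt(2 p_j (1 - p_j) N)`, two-sided
#' Wald p-values, and an INFO value drawn uniformly on a configurable range
#' to exercise imputation-quality filters.
#'
#' Monomorphic variants (frequency 0 or 1) have an undefined SE; they are
#' emitted with missing statistics and flagged in the `flag` column.
#'
#' @param effect_panel An `effect_panel`.
#' @param disorder Disorder name (a `beta_<disorder>` column must exist).
#' @param gwas_n Training sample size (> 0).
#' @param seed Integer seed.
#' @param info_range Range of the uniform INFO draw (default (0.4, 1.1]).
#' @return A `summary_stats` data.frame with columns
#'   SNP CHR BP A1 A2 BETA SE P INFO FRQ N (+ `flag`).
#' @export
simulate_sumstats <- function(effect_panel, disorder, gwas_n, seed,
                              info_range = c(0.4, 1.1)) {
  if (gwas_n <= 0) stop_famprs("gwas_n must be positive")
  bcol <- paste0("beta_", disorder)
  if (!bcol %in% names(effect_panel))
    stop_famprs("no effects for disorder ", disorder)
  p <- effect_panel$maf
  mono <- p <= 0 | p >= 1
  se <- ifelse(mono, NA_real_, 1 / sqrt(2 * p * (1 - p) * gwas_n))
  with_substream(seed, paste0("sumstats_", disorder), {
    bhat <- effect_panel[[bcol]] + ifelse(mono, NA_real_, rnorm(length(p)) * se)
    info <- runif(length(p), info_range[1], info_range[2])
  })
  pval <- 2 * pnorm(-abs(bhat / se))
  out <- data.frame(SNP = effect_panel$variant_id, CHR = effect_panel$chr,
                    BP = effect_panel$bp, A1 = effect_panel$a1,
                    A2 = effect_panel$a2, BETA = bhat, SE = se, P = pval,
                    INFO = info, FRQ = p, N = unname(gwas_n),
                    flag = ifelse(mono, "monomorphic", ""),
                    stringsAsFactors = FALSE)
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Simulate summary statistics under the LD-score regression model
#'
#' Generates per-variant z-scores (and derived BETA/SE/P) for one or two
#' traits directly from the polygenic model with block-exchangeable LD:
#' within blocks of `block_size` variants pairwise haplotype correlation is
#' `rho`, so every variant's LD score is `l_j = 1 + (block_size - 1) rho^2`.
#' Marginal z-scores are `z = sqrt(N) R u + e`, `e ~ N(0, R)`, giving
#' `E[chi^2_j] = 1 + N h2 l_j / M` — the regression the estimator fits.
#' Mixing block sizes yields variation in `l_j` (needed to identify the
#' slope), so `block_size` may be a vector from which each block's size is
#' sampled.
#'
#' @param m Number of variants.
#' @param n Sample size (length 1 or 2 for a bivariate pair).
#' @param h2 Heritability (length matching `n`).
#' @param rg Genetic correlation between the two traits (bivariate case).
#' @param block_size Integer vector of candidate block sizes.
#' @param rho Within-block haplotype correlation.
#' @param seed Integer seed.
#' @return list with `stats` (list of `summary_stats`, one per trait),
#'   `ld_scores` (data.frame SNP, L2) and `M`.
#' @export
simulate_ldsc_stats <- function(m, n, h2, rg = 0, block_size = c(1, 5, 10, 20),
                                rho = 0.9, seed = 1L) {
  k <- length(n)
  stopifnot(length(h2) == k, k %in% 1:2)
  with_substream(seed, "ldsc_sim", {
    sizes <- integer(0)
    while (sum(sizes) < m)
      sizes <- c(sizes, sample(block_size, 1))
    sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - m)
    sizes <- sizes[sizes > 0]
    blk <- rep(seq_along(sizes), sizes)
    l_j <- 1 + (sizes[blk] - 1) * rho^2
    # true standardised effects, correlated rg across traits
    D <- diag(sqrt(h2 / m), k)
    C <- if (k == 2) matrix(c(1, rg, rg, 1), 2) else matrix(1)
    u <- matrix(rnorm(m * k), m) %*% chol_psd(D %*% C %*% D)
    stats <- vector("list", k)
    maf <- runif(m, 0.1, 0.5)
    for (t in seq_len(k)) {
      z <- numeric(m)
      for (b in seq_along(sizes)) {
        idx <- which(blk == b)
        s <- length(idx)
        R <- matrix(rho, s, s); diag(R) <- 1
        Lc <- chol_psd(R)
        mu <- sqrt(n[t]) * as.numeric(R %*% u[idx, t])
        z[idx] <- mu + as.numeric(t(Lc) %*% rnorm(s))
      }
      se <- 1 / sqrt(2 * maf * (1 - maf) * n[t])
      out <- data.frame(SNP = sprintf("snp%05d", seq_len(m)),
                        CHR = 1L, BP = seq_len(m) * 1000L,
                        A1 = "A", A2 = "G",
                        BETA = z * se, SE = se,
                        P = 2 * pnorm(-abs(z)),
                        INFO = 1, FRQ = maf, N = n[t],
                        stringsAsFactors = FALSE)
      class(out) <- c("summary_stats", "data.frame")
      stats[[t]] <- out
    }
  })
  list(stats = stats,
       ld_scores = data.frame(SNP = sprintf("snp%05d", seq_len(m)), L2 = l_j),
       M = m)
}
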