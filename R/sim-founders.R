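#' Ground-truth effect panel for the simulator
#'
#' Draws per-variant allele frequencies and true liability-scale effects
#' for all configured disorders.  Standardised-scale effects are drawn
#' jointly multivariate normal across disorders so that (i) the aggregate
#' genetic liability of disorder d has variance `h2[d]`, and (ii) effects
#' for each disorder pair have the configured genetic correlation.
#' Per-allele effects are the standardised effects divided by
#' `sqrt(2 p (1-p))`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to the config master seed).
#' @return data.frame of class `effect_panel`: `variant_id`, `chr`, `bp`,
#'   `a1`, `a2`, `maf`, one `beta_<disorder>` column per disorder (per-allele
#'   scale), and one `causal_<disorder>` flag per disorder.  The
#'   standardised-scale effect matrix is kept in attribute `u`.
#' @export
make_effect_panel <- function(config, seed = config$seed) {
  m <- config$n_variants
  d <- config$disorders
  with_substream(seed, "effects", {
    maf <- runif(m, config$maf_range[1], config$maf_range[2])
    causal <- matrix(runif(m * length(d)) < config$prop_causal, m,
                     dimnames = list(NULL, d))
    m_causal <- pmax(colSums(causal), 1L)
    # u: standardised-genotype effects, Cov(u_j) = D^{1/2} R D^{1/2},
    # D = h2 / m_causal, so sum_j u_j^2 ~ h2 per disorder under LE.
    R <- config$genetic_correlation
    sc <- sqrt(config$h2 / m_causal)
    Sigma <- diag(sc, length(d)) %*% R %*% diag(sc, length(d))
    L <- chol_psd(Sigma)
    u <- matrix(rnorm(m * length(d)), m) %*% L
    colnames(u) <- d
    u[!causal] <- 0
    beta <- u / sqrt(2 * maf * (1 - maf))
  })
  out <- data.frame(
    variant_id = sprintf("snp%05d", seq_len(m)),
    chr = ((seq_len(m) - 1L) %% 22L) + 1L,
    bp = 10000L + 1000L * seq_len(m),
    a1 = "A", a2 = "G", maf = maf,
    stringsAsFactors = FALSE
  )
  for (k in d) out[[paste0("beta_", k)]] <- beta[, k]
  for (k in d) out[[paste0("causal_", k)]] <- causal[, k]
  attr(out, "u") <- u
  attr(out, "disorders") <- d
  class(out) <- c("effect_panel", "data.frame")
  out
}

# Cholesky factor tolerant of semi-definite matrices.
chol_psd <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, 0)
  t(e$vectors %*% (t(e$vectors) * sqrt(v)))
}

#' Simulate founder genotypes
#'
#' Draws unrelated, phased genotypes: per variant, each haplotype carries
#' the A1 allele with probability `maf`.  Variants are in linkage
#' equilibrium by default; the optional `ld` argument switches on a
#' block-exchangeable correlation structure (a Gaussian copula thresholded
#' at the allele frequency) to exercise LD pruning and LD-score code.
#'
#' @param n_subjects Number of founders to draw.
#' @param effect_panel An [make_effect_panel()] result (supplies MAFs and
#'   variant metadata).
#' @param seed Integer seed.
#' @param ld `NULL` for linkage equilibrium, or `list(block_size =, rho =)`
#'   for exchangeable within-block haplotype correlation `rho`.
#' @param ids Optional subject ids.
#' @return A phased [dosage_panel()].
#' @export
simulate_founders <- function(n_subjects, effect_panel, seed, ld = NULL,
                              ids = NULL) {
  maf <- effect_panel$maf
  if (anyNA(maf) || any(!is.finite(maf)))
    stop_famprs("non-finite MAF in effect panel")
  if (any(maf < 0 | maf > 1)) stop_famprs("MAF outside [0,1]")
  m <- length(maf)
  draw_hap <- function() {
    if (is.null(ld)) {
      matrix(runif(n_subjects * m) < rep(maf, each = n_subjects),
             n_subjects, m) + 0L
    } else {
      b <- ld$block_size
      rho <- ld$rho
      z <- matrix(rnorm(n_subjects * m), n_subjects, m)
      # shared block factor: z_j = sqrt(rho) f_block + sqrt(1-rho) e_j
      blk <- ((seq_len(m) - 1L) %/% b) + 1L
      f <- matrix(rnorm(n_subjects * max(blk)), n_subjects, max(blk))
      z <- sqrt(rho) * f[, blk, drop = FALSE] + sqrt(1 - rho) * z
      (z < rep(qnorm(maf), each = n_subjects)) + 0L
    }
  }
  with_substream(seed, "founders", {
    h1 <- draw_hap()
    h2 <- draw_hap()
  })
  dos <- h1 + h2
  rownames(dos) <- rownames(h1) <- rownames(h2) <-
    ids %||% sprintf("U%05d", seq_len(n_subjects))
  dosage_panel(dos, effect_panel[c("variant_id", "chr", "bp", "a1", "a2",
                                   "maf")],
               h1 = h1, h2 = h2)
}

#' True (standardised) genetic scores for a panel
#'
#' Computes G_d = sum_j u_jd x_ij / ||u_d||, the unit-variance genetic
#' liability component per disorder, with x the theoretical
#' centred/standardised dosage.  Normalising by the realised effect norm
#' (rather than sqrt(h2)) keeps Var(G) = 1 for finite variant panels, so
#' configured prevalences are met exactly in expectation.
#'
#' @param panel A `dosage_panel`.
#' @param effect_panel The matching `effect_panel`.
#' @param h2 Named heritabilities (columns with h2 = 0 give zero scores).
#' @return Matrix subjects x disorders of standardised genetic scores.
#' @export
true_genetic_scores <- function(panel, effect_panel, h2) {
  u <- attr(effect_panel, "u")
  maf <- effect_panel$maf
  x <- sweep(panel$dosage, 2, 2 * maf)
  x <- sweep(x, 2, sqrt(pmax(2 * maf * (1 - maf), 1e-12)), "/")
  g <- x %*% u
  for (k in colnames(g)) {
    nrm <- sqrt(sum(u[, k]^2))
    if (nrm > 0) g[, k] <- g[, k] / nrm
  }
  g
}
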