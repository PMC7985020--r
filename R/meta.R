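# Orient `stats` to the allele coding of `reference` variant by variant.
# Swapped allele pairs get beta negated and frequency complemented;
# variants absent from the reference or with a discordant pair are dropped.
orient_to_reference <- function(reference, stats) {
  idx <- match(stats$SNP, reference$SNP)
  keep <- !is.na(idx)
  stats <- stats[keep, , drop = FALSE]
  ref <- reference[idx[keep], , drop = FALSE]
  same <- toupper(stats$A1) == toupper(ref$A1) &
    toupper(stats$A2) == toupper(ref$A2)
  swapped <- toupper(stats$A1) == toupper(ref$A2) &
    toupper(stats$A2) == toupper(ref$A1)
  out <- stats[same | swapped, , drop = FALSE]
  sw <- swapped[same | swapped]
  out$BETA[sw] <- -out$BETA[sw]
  out$FRQ[sw] <- 1 - out$FRQ[sw]
  out$A1 <- ref$A1[same | swapped]
  out$A2 <- ref$A2[same | swapped]
  rownames(out) <- NULL
  out
}

#' Select the shared cross-disorder variant set
#'
#' After orienting all three statistics to a common effect allele, retains
#' variants associated at `p < p_max` in every study whose effects point in
#' the same direction across all three.  Concordance is evaluated on the
#' common-allele orientation, before any positive flipping.
#'
#' @param s_bd,s_scz,s_mdd `summary_stats` for the three disorders.
#' @param p_max Per-study inclusion threshold (default 0.05).
#' @return Character vector of variant ids (order of the first input).
#' @export
select_shared <- function(s_bd, s_scz, s_mdd, p_max = 0.05) {
  s2 <- orient_to_reference(s_bd, s_scz)
  s3 <- orient_to_reference(s_bd, s_mdd)
  ids <- Reduce(intersect, list(s_bd$SNP, s2$SNP, s3$SNP))
  b <- cbind(s_bd$BETA[match(ids, s_bd$SNP)],
             s2$BETA[match(ids, s2$SNP)],
             s3$BETA[match(ids, s3$SNP)])
  p <- cbind(s_bd$P[match(ids, s_bd$SNP)],
             s2$P[match(ids, s2$SNP)],
             s3$P[match(ids, s3$SNP)])
  ok <- apply(p < p_max, 1, all) &
    (apply(b > 0, 1, all) | apply(b < 0, 1, all))
  ids[which(ok)]
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Vectorised over variants: given a variants-by-studies matrix of effects
#' and standard errors, computes the method-of-moments between-study
#' variance `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))` from
#' Cochran's Q with fixed-effects weights `w = 1/SE^2`, then combines with
#' random-effects weights `1/(SE^2 + tau2)`.
#'
#' @param betas,ses Numeric matrices (variants x studies) or vectors
#'   (one variant).
#' @return data.frame: `beta`, `se`, `p` (two-sided Wald), `tau2`, `Q`, `k`.
#' @export
random_effects_meta <- function(betas, ses) {
  if (is.null(dim(betas))) betas <- matrix(betas, nrow = 1)
  if (is.null(dim(ses))) ses <- matrix(ses, nrow = 1)
  if (!identical(dim(betas), dim(ses)))
    stop_famprs("betas and ses must have matching dimensions")
  if (ncol(betas) < 2) stop_famprs("meta-analysis needs k >= 2 studies")
  if (any(ses <= 0, na.rm = TRUE) || anyNA(ses))
    stop_famprs("all standard errors must be positive")
  k <- ncol(betas)
  w <- 1 / ses^2
  sw <- rowSums(w)
  beta_fe <- rowSums(w * betas) / sw
  Q <- rowSums(w * (betas - beta_fe)^2)
  denom <- sw - rowSums(w^2) / sw
  tau2 <- pmax(0, (Q - (k - 1)) / denom)
  ws <- 1 / (ses^2 + tau2)
  beta_re <- rowSums(ws * betas) / rowSums(ws)
  se_re <- 1 / sqrt(rowSums(ws))
  data.frame(beta = beta_re, se = se_re,
             p = 2 * pnorm(-abs(beta_re / se_re)),
             tau2 = tau2, Q = Q, k = k)
}

#' Shared-disorder PRS summary statistics
#'
#' Builds the cross-disorder score weights: orient to a common allele,
#' apply [select_shared()], then random-effects meta-analysis of the three
#' per-variant effects.  Output is a standard `summary_stats` table (INFO
#' is the per-variant minimum across studies; FRQ and N from the first
#' study) that the PRS engine consumes unchanged.
#'
#' @inheritParams select_shared
#' @return A `summary_stats` data.frame for the shared variant set.
#' @export
shared_meta_stats <- function(s_bd, s_scz, s_mdd, p_max = 0.05) {
  ids <- select_shared(s_bd, s_scz, s_mdd, p_max = p_max)
  if (!length(ids)) stop_famprs("no shared concordant variants at p < ", p_max)
  s2 <- orient_to_reference(s_bd, s_scz)
  s3 <- orient_to_reference(s_bd, s_mdd)
  i1 <- match(ids, s_bd$SNP); i2 <- match(ids, s2$SNP); i3 <- match(ids, s3$SNP)
  b <- cbind(s_bd$BETA[i1], s2$BETA[i2], s3$BETA[i3])
  s <- cbind(s_bd$SE[i1], s2$SE[i2], s3$SE[i3])
  me <- random_effects_meta(b, s)
  out <- data.frame(SNP = ids, CHR = s_bd$CHR[i1], BP = s_bd$BP[i1],
                    A1 = s_bd$A1[i1], A2 = s_bd$A2[i1],
                    BETA = me$beta, SE = me$se, P = me$p,
                    INFO = pmin(s_bd$INFO[i1], s2$INFO[i2], s3$INFO[i3]),
                    FRQ = s_bd$FRQ[i1], N = s_bd$N[i1],
                    stringsAsFactors = FALSE)
  attr(out, "tau2") <- me$tau2
  attr(out, "Q") <- me$Q
  attr(out, "estimator") <- "DerSimonian-Laird"
  class(out) <- c("summary_stats", "data.frame")
  out
}
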