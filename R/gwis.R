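#' Disorder-specific (conditional) summary statistics
#'
#' Derives the "unique liability" statistics of a target disorder after
#' removing the genetically shared component with a covariate disorder:
#' with correction coefficient `b = rho_g / h2_cov`, per variant
#' `beta* = beta_target - b * beta_cov` and, assuming non-overlapping
#' training samples, `SE* = sqrt(SE_target^2 + b^2 SE_cov^2)`; two-sided
#' Wald p-values.  Inputs are expected to be INFO-filtered to [0.9, 1.1]
#' beforehand (see [filter_info()]); the covariate is oriented to the
#' target's effect alleles and only shared variants are emitted.
#'
#' @param target,covariate `summary_stats` for the two disorders.
#' @param h2_cov Liability heritability of the covariate disorder (> 0).
#' @param rho_g Coheritability of target and covariate.
#' @return A `summary_stats` with corrected BETA/SE/P; the correction
#'   coefficient is stored in attribute `b`.
#' @export
gwis_correct <- function(target, covariate, h2_cov, rho_g) {
  if (h2_cov <= 0) stop_famprs("h2_cov must be positive")
  b <- rho_g / h2_cov
  covariate <- orient_to_reference(target, covariate)
  ids <- intersect(target$SNP, covariate$SNP)
  if (!length(ids)) stop_famprs("no shared variants for the GWIS correction")
  it <- match(ids, target$SNP); ic <- match(ids, covariate$SNP)
  beta <- target$BETA[it] - b * covariate$BETA[ic]
  se <- sqrt(target$SE[it]^2 + b^2 * covariate$SE[ic]^2)
  out <- data.frame(SNP = ids, CHR = target$CHR[it], BP = target$BP[it],
                    A1 = target$A1[it], A2 = target$A2[it],
                    BETA = beta, SE = se, P = 2 * pnorm(-abs(beta / se)),
                    INFO = target$INFO[it], FRQ = target$FRQ[it],
                    N = target$N[it], stringsAsFactors = FALSE)
  attr(out, "b") <- b
  class(out) <- c("summary_stats", "data.frame")
  out
}
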