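#' Read GWAS summary statistics from a tab-delimited file
#'
#' Requires columns SNP, A1, A2, P and either BETA or OR (OR is converted
#' to `BETA = log(OR)`); SE, INFO, FRQ, N, CHR, BP are optional and left
#' missing (never imputed) when absent.  Records with identical effect and
#' other allele are rejected with a warning; duplicated variant ids are an
#' error.
#'
#' @param path Input TSV path.
#' @return A `summary_stats` data.frame.
#' @export
read_sumstats <- function(path) {
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE)
  req <- c("SNP", "A1", "A2", "P")
  miss <- setdiff(req, names(dt))
  if (length(miss))
    stop_famprs("summary statistics missing required column(s): ",
                paste(miss, collapse = ", "))
  if (!"BETA" %in% names(dt)) {
    if (!"OR" %in% names(dt))
      stop_famprs("summary statistics need a BETA or OR column")
    dt$BETA <- log(dt$OR)
  }
  dup <- unique(dt$SNP[duplicated(dt$SNP)])
  if (length(dup))
    stop_famprs("duplicated variant id(s): ", paste(dup, collapse = ", "))
  same <- toupper(dt$A1) == toupper(dt$A2)
  if (any(same)) {
    warning(sum(same), " record(s) with A1 == A2 rejected")
    dt <- dt[!same, , drop = FALSE]
  }
  for (opt in c("CHR", "BP", "SE", "INFO", "FRQ", "N"))
    if (!opt %in% names(dt)) dt[[opt]] <- NA
  out <- dt[c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "P", "INFO",
              "FRQ", "N")]
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' @rdname read_sumstats
#' @param stats A `summary_stats` data.frame.
#' @export
write_sumstats <- function(stats, path) {
  data.table::fwrite(as.data.frame(stats)[
    c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "P", "INFO", "FRQ", "N")],
    path, sep = "\t")
  invisible(path)
}

#' Flip alleles so every effect size is positive
#'
#' For each variant with a negative effect the allele labels are swapped,
#' the effect negated, and the effect-allele frequency replaced by its
#' complement; p-values and |BETA| are untouched.  After harmonisation the
#' PRS built from these weights is a cumulative additive risk load.
#' Idempotent.
#'
#' @param stats A `summary_stats` data.frame with BETA present.
#' @return The harmonised `summary_stats`.
#' @export
harmonize_positive <- function(stats) {
  if (anyNA(stats$BETA))
    stop_famprs("BETA missing for some variants; filter before harmonising")
  neg <- stats$BETA < 0
  a1 <- stats$A1
  stats$A1[neg] <- stats$A2[neg]
  stats$A2[neg] <- a1[neg]
  stats$BETA[neg] <- -stats$BETA[neg]
  stats$FRQ[neg] <- 1 - stats$FRQ[neg]
  stats
}

#' Filter variants by imputation quality
#'
#' Retains variants with `lo <= INFO <= hi` (both bounds inclusive: the
#' conventions "INFO < 0.6 removed" and "INFO > 1.1 removed" keep the
#' boundary values).  Variants lacking INFO are dropped unless
#' `keep_missing = TRUE`.
#'
#' @param stats A `summary_stats` data.frame.
#' @param lo,hi Inclusive INFO bounds (`hi` may be `Inf`).
#' @param keep_missing Keep variants with missing INFO?
#' @return The filtered `summary_stats`.
#' @export
filter_info <- function(stats, lo = 0.6, hi = Inf, keep_missing = FALSE) {
  if (lo > hi) stop_famprs("filter_info: lo must not exceed hi")
  ok <- !is.na(stats$INFO) & stats$INFO >= lo & stats$INFO <= hi
  if (keep_missing) ok <- ok | is.na(stats$INFO)
  out <- stats[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Align summary statistics to a genotype panel
#'
#' Matches variants by id, requires the same unordered allele pair, and
#' records per variant whether the panel dosage already counts the risk
#' (effect) allele or must be complemented (`d -> 2 - d`).  Unmatched and
#' allele-discordant variants are dropped and tallied in the `drop_log`
#' attribute.
#'
#' @param stats A positively harmonised `summary_stats`.
#' @param panel A `dosage_panel`.
#' @return data.frame of class `aligned_variants` with `variant_id`,
#'   `weight` (>= 0), `p`, and `flip` (logical); attribute `drop_log` is a
#'   data.frame (variant_id, reason).
#' @export
align_to_panel <- function(stats, panel) {
  if (any(stats$BETA < 0))
    stop_famprs("stats must be harmonised to positive effects first")
  idx <- match(stats$SNP, panel$variants$variant_id)
  reason <- rep(NA_character_, nrow(stats))
  reason[is.na(idx)] <- "absent_from_panel"
  pv <- panel$variants[ifelse(is.na(idx), 1L, idx), , drop = FALSE]
  same <- toupper(stats$A1) == toupper(pv$a1) &
    toupper(stats$A2) == toupper(pv$a2)
  swapped <- toupper(stats$A1) == toupper(pv$a2) &
    toupper(stats$A2) == toupper(pv$a1)
  disc <- is.na(reason) & !(same | swapped)
  reason[disc] <- "allele_mismatch"
  keep <- is.na(reason)
  if (!any(keep))
    stop_famprs("no variants shared between statistics and panel")
  out <- data.frame(variant_id = stats$SNP[keep],
                    weight = stats$BETA[keep],
                    p = stats$P[keep],
                    flip = swapped[keep],
                    stringsAsFactors = FALSE)
  attr(out, "drop_log") <- data.frame(variant_id = stats$SNP[!keep],
                                      reason = reason[!keep],
                                      stringsAsFactors = FALSE)
  class(out) <- c("aligned_variants", "data.frame")
  out
}
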