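#' Select variants below a training p-value threshold
#'
#' Retains variants with `p < p_thr` (strict inequality).  Variants with
#' missing p are never selected except at `p_thr = 1`, where every variant
#' with a defined p-value is kept.
#'
#' @param stats A `summary_stats` or `aligned_variants` data.frame (any
#'   data.frame with a `P` or `p` column).
#' @param p_thr Threshold in (0, 1].
#' @return The selected subset, same class as the input.
#' @export
select_by_threshold <- function(stats, p_thr) {
  if (p_thr <= 0 || p_thr > 1) stop_famprs("p_thr must lie in (0,1]")
  p <- stats[["P"]] %||% stats[["p"]]
  keep <- !is.na(p) & (p < p_thr | p_thr == 1)
  out <- stats[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score subjects over an aligned variant set
#'
#' Raw score `S_i = sum_j w_j d_ij` with the dosage oriented to the risk
#' allele (complemented where the alignment flags it), and the relative
#' risk-load scaling `scaled_i = S_i / (2 sum_j w_j)` so that 0 is the
#' minimum and 1 the maximum attainable cumulative risk load.  Missing
#' dosages are mean-imputed from the test sample (2x the sample effect
#' allele frequency); the number of imputed entries is recorded.
#'
#' @param panel A `dosage_panel`.
#' @param variants An `aligned_variants` set (weights all >= 0, >= 1 row).
#' @return data.frame `subject_id`, `raw`, `scaled`, with attributes
#'   `n_snps` and `n_imputed`.
#' @export
prs_score <- function(panel, variants) {
  if (nrow(variants) == 0) stop_famprs("empty variant set: nothing to score")
  if (any(variants$weight < 0)) stop_famprs("weights must be non-negative")
  j <- match(variants$variant_id, panel$variants$variant_id)
  if (anyNA(j))
    stop_famprs("aligned variants missing from panel: ",
                paste(head(variants$variant_id[is.na(j)], 5), collapse = ", "))
  D <- panel$dosage[, j, drop = FALSE]
  rng <- range(D, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) {
    bad <- which(colSums(D < 0 | D > 2, na.rm = TRUE) > 0)[1]
    stop_famprs("dosage outside [0,2] for variant ",
                panel$variants$variant_id[j[bad]])
  }
  n_imp <- sum(is.na(D))
  if (n_imp > 0) {
    mu <- colMeans(D, na.rm = TRUE)
    idx <- which(is.na(D), arr.ind = TRUE)
    D[idx] <- mu[idx[, 2]]
  }
  flip <- variants$flip %||% rep(FALSE, nrow(variants))
  if (any(flip)) D[, flip] <- 2 - D[, flip, drop = FALSE]
  raw <- as.numeric(D %*% variants$weight)
  wsum <- sum(variants$weight)
  scaled <- if (wsum > 0) raw / (2 * wsum) else rep(0, length(raw))
  out <- data.frame(subject_id = rownames(panel$dosage), raw = raw,
                    scaled = scaled, stringsAsFactors = FALSE)
  attr(out, "n_snps") <- nrow(variants)
  attr(out, "n_imputed") <- n_imp
  out
}

#' Z-score standardisation over an analysis sample
#'
#' Centres and scales with the sample standard deviation (n-1 denominator)
#' computed over exactly the subjects entering the model, so odds ratios
#' from different scores are per-SD and comparable.
#'
#' @param x Numeric scores (length >= 2, nonzero variance).
#' @return Standardised numeric vector.
#' @export
zstandardize <- function(x) {
  if (length(x) < 2) stop_famprs("need at least two subjects to standardise")
  s <- sd(x)
  if (!is.finite(s) || s == 0)
    stop_famprs("zero variance: degenerate score cannot be standardised")
  (x - mean(x)) / s
}

#' PRS profile across the threshold grid
#'
#' Computes raw, scaled and standardised scores for one score type at each
#' threshold of the grid.  Thresholds at which no variant survives are
#' skipped (recorded in the `skipped` attribute).
#'
#' @param panel A `dosage_panel` restricted to the analysis subjects.
#' @param stats Harmonised, INFO-filtered `summary_stats`.
#' @param score_type Label stored in the output.
#' @param thresholds Numeric vector of p-value cutoffs.
#' @return data.frame of class `prs_profile`: `subject_id`, `score_type`,
#'   `threshold`, `raw`, `scaled`, `z`, `n_snps`.
#' @export
prs_profile <- function(panel, stats, score_type = "PRS",
                        thresholds = prs_thresholds()) {
  aligned <- align_to_panel(harmonize_positive(stats), panel)
  rows <- list(); skipped <- numeric(0)
  for (thr in thresholds) {
    sel <- select_by_threshold(aligned, thr)
    if (nrow(sel) == 0) {
      skipped <- c(skipped, thr)
      next
    }
    sc <- prs_score(panel, sel)
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = sc$subject_id, score_type = score_type, threshold = thr,
      raw = sc$raw, scaled = sc$scaled,
      z = if (sd(sc$raw) > 0) zstandardize(sc$raw) else NA_real_,
      n_snps = attr(sc, "n_snps"), stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop_famprs("no threshold retained any variant")
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  class(out) <- c("prs_profile", "data.frame")
  out
}

#' Write a PRS profile as TSV
#' @param profile A `prs_profile`.
#' @param path Output path.
#' @export
write_prs_profile <- function(profile, path) {
  data.table::fwrite(as.data.frame(profile), path, sep = "\t")
  invisible(path)
}
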