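#' Greedy sliding-window LD pruning
#'
#' Within each window of `window` variants, repeatedly drops the
#' later-positioned member of any pair whose squared Pearson dosage
#' correlation exceeds `r2_max`, then advances by `step`.  Monomorphic
#' variants (undefined correlation) are removed first and logged in the
#' `removed` attribute.
#'
#' @param panel A `dosage_panel`.
#' @param window Window size in variants (>= step).
#' @param step Window advance (>= 1).
#' @param r2_max Maximum tolerated r-squared in (0, 1].
#' @return The pruned `dosage_panel`; attribute `removed` is a data.frame
#'   (variant_id, reason).
#' @export
prune_ld <- function(panel, window = 50L, step = 5L, r2_max = 0.5) {
  if (step < 1 || window < step) stop_famprs("need window >= step >= 1")
  if (r2_max <= 0 || r2_max > 1) stop_famprs("r2_max must lie in (0,1]")
  D <- panel$dosage
  sds <- apply(D, 2, sd)
  mono <- sds == 0
  removed <- data.frame(variant_id = panel$variants$variant_id[mono],
                        reason = rep("monomorphic", sum(mono)),
                        stringsAsFactors = FALSE)
  keep_idx <- which(!mono)
  alive <- rep(TRUE, length(keep_idx))
  Z <- scale(D[, keep_idx, drop = FALSE])
  n <- nrow(D)
  start <- 1L
  m <- length(keep_idx)
  while (start <= m) {
    win <- start:min(start + window - 1L, m)
    win <- win[alive[win]]
    if (length(win) > 1) {
      r2 <- (crossprod(Z[, win, drop = FALSE]) / (n - 1))^2
      for (a in seq_along(win)) {
        if (!alive[win[a]]) next
        hits <- which(r2[a, ] > r2_max + 1e-12)
        hits <- hits[hits > a & alive[win[hits]]]
        alive[win[hits]] <- FALSE
      }
    }
    if (start + window - 1L >= m) break
    start <- start + step
  }
  pruned <- removed
  if (any(!alive))
    pruned <- rbind(removed, data.frame(
      variant_id = panel$variants$variant_id[keep_idx[!alive]],
      reason = "high_ld", stringsAsFactors = FALSE))
  out <- subset_panel(panel, variants = keep_idx[alive])
  attr(out, "removed") <- pruned
  out
}

#' Genetic relationship matrix (centred-standardised)
#'
#' `K = (1/m) sum_j x_j x_j'` with `x_ij = (d_ij - 2 p_j) /
#' sqrt(2 p_j (1 - p_j))` and `p_j` the sample allele frequency; the
#' GEMMA-style standardised kinship.  Monomorphic variants are skipped.
#' A small ridge (1e-6) is added to the diagonal so the matrix stays
#' numerically positive definite.
#'
#' @param panel A `dosage_panel` (>= 2 subjects, >= 1 polymorphic variant).
#' @param ridge Diagonal ridge (default 1e-6).
#' @return Symmetric matrix of class `grm` with subject dimnames and
#'   attribute `m` (variants used).
#' @export
compute_grm <- function(panel, ridge = 1e-6) {
  D <- panel$dosage
  if (nrow(D) < 2) stop_famprs("need at least two subjects")
  p <- colMeans(D) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop_famprs("no polymorphic variants for the GRM")
  X <- sweep(D[, poly, drop = FALSE], 2, 2 * p[poly])
  X <- sweep(X, 2, sqrt(2 * p[poly] * (1 - p[poly])), "/")
  K <- tcrossprod(X) / sum(poly)
  K <- (K + t(K)) / 2 + diag(ridge, nrow(K))
  dimnames(K) <- list(rownames(D), rownames(D))
  structure(K, m = sum(poly), class = c("grm", "matrix"))
}

#' Write a GRM as a square TSV with subject header
#' @param K A `grm`.
#' @param path Output path.
#' @export
write_grm <- function(K, path) {
  dt <- data.table::as.data.table(unclass(K))
  data.table::fwrite(cbind(data.table::data.table(iid = rownames(K)), dt),
                     path, sep = "\t")
  invisible(path)
}
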