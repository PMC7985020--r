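#' Assign diagnoses under a correlated liability-threshold model
#'
#' Per subject and disorder d, liability is
#' `L_d = sqrt(h2_d) G_d + sqrt(1 - h2_d) E_d`, with `G_d` the standardised
#' true genetic score and `E_d` multivariate normal across disorders with
#' the configured residual correlation.  A disorder is expressed when
#' liability exceeds the upper-prevalence quantile of the standard normal;
#' the reported diagnosis gives BD precedence over MDD, and subjects
#' exceeding neither threshold are `unaffected`.
#'
#' Interview ages and (for affected subjects) onset ages are drawn with no
#' generational trend, so anticipation analyses are null by construction.
#'
#' @param dosages A `dosage_panel`.
#' @param effect_panel The matching `effect_panel`.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param pedigree Optional pedigree data.frame (`fid`, `iid`, `pat`, `mat`,
#'   `sex`, `generation`, `married_in`); when `NULL` subjects are treated as
#'   unrelated singletons.
#' @param cohort Cohort label stamped on every subject ("FAM" or "CC").
#' @return A `pedigree_cohort` data.frame (one row per subject) with
#'   diagnosis, per-disorder affection flags, covariates, and the liability
#'   and genetic-score matrices in attributes `liability` and `gscore`.
#' @export
assign_phenotypes <- function(dosages, effect_panel, config, seed,
                              pedigree = NULL, cohort = "CC") {
  d <- config$disorders
  G <- true_genetic_scores(dosages, effect_panel, config$h2)
  n <- nrow(G)
  Re <- config$env_correlation
  if (min(eigen(Re, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop_famprs("residual correlation matrix is not positive semi-definite")
  with_substream(seed, "environment", {
    E <- matrix(rnorm(n * length(d)), n) %*% chol_psd(Re)
    colnames(E) <- d
    L <- sweep(G, 2, sqrt(config$h2[d]), "*") +
      sweep(E, 2, sqrt(1 - config$h2[d]), "*")
    Tq <- qnorm(1 - config$prevalence[d])
    aff <- sweep(L, 2, Tq, ">")
    diagnosis <- ifelse(aff[, "BD"], "BD",
                        ifelse(aff[, "MDD"], "MDD", "unaffected"))
    age_interview <- round(runif(n, 25, 75))
    age_onset <- ifelse(diagnosis == "unaffected", NA_real_,
                        pmin(pmax(round(rnorm(n, 30, 8)), 10), 60))
  })
  ids <- rownames(dosages$dosage)
  if (is.null(pedigree)) {
    out <- data.frame(fid = ids, iid = ids, pat = "0", mat = "0",
                      sex = sample(1:2, n, replace = TRUE),
                      generation = 1L, married_in = FALSE,
                      stringsAsFactors = FALSE)
  } else {
    out <- pedigree[match(ids, pedigree$iid), , drop = FALSE]
    if (anyNA(out$iid))
      stop_famprs("pedigree does not cover all panel subjects")
  }
  out$cohort <- cohort
  out$diagnosis <- diagnosis
  for (k in d) out[[paste0("aff_", k)]] <- aff[, k]
  out$age_interview <- age_interview
  out$age_onset <- age_onset
  rownames(out) <- NULL
  attr(out, "liability") <- L
  attr(out, "gscore") <- G
  class(out) <- c("pedigree_cohort", "data.frame")
  out
}

#' Retain multiplex families
#'
#' Keeps only families with at least `min_affected` BD cases.  Generation
#' index and married-in flags are carried through from the pedigree.
#'
#' @param cohort A `pedigree_cohort`.
#' @param min_affected Minimum BD cases per retained family; 0 keeps all.
#' @return The filtered `pedigree_cohort` (liability/gscore attributes
#'   subset accordingly).
#' @export
ascertain_multiplex <- function(cohort, min_affected) {
  if (min_affected < 0) stop_famprs("min_affected must be >= 0")
  if (min_affected == 0) return(cohort)
  n_bd <- tapply(cohort$diagnosis == "BD", cohort$fid, sum)
  keep_f <- names(n_bd)[n_bd >= min_affected]
  keep <- cohort$fid %in% keep_f
  out <- cohort[keep, , drop = FALSE]
  for (a in c("liability", "gscore"))
    if (!is.null(attr(cohort, a)))
      attr(out, a) <- attr(cohort, a)[keep, , drop = FALSE]
  class(out) <- class(cohort)
  rownames(out) <- NULL
  out
}

#' Write a cohort as PLINK .fam plus a phenotype TSV
#'
#' @param cohort A `pedigree_cohort`.
#' @param fam_path,pheno_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, fam_path, pheno_path) {
  fam <- data.frame(FID = cohort$fid, IID = cohort$iid, PAT = cohort$pat,
                    MAT = cohort$mat, SEX = cohort$sex,
                    PHENO = ifelse(cohort$diagnosis == "BD", 2L, 1L))
  data.table::fwrite(fam, fam_path, sep = "\t", col.names = FALSE)
  ph <- cohort[c("fid", "iid", "diagnosis", "cohort", "generation",
                 "married_in", "age_interview", "age_onset")]
  data.table::fwrite(ph, pheno_path, sep = "\t")
  invisible(c(fam_path, pheno_path))
}
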