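#' Default contrast definitions
#'
#' Each contrast names two disjoint subject groups (group 1 is the focal,
#' hypothesised-higher group), the covariates, and whether married-in
#' family members are excluded.  Group selectors are quoted expressions on
#' the cohort columns.
#'
#' @return Named list of contrast specs.
#' @export
default_contrasts <- function() {
  list(
    FAM_BD_vs_CC_controls = list(
      g1 = quote(cohort == "FAM" & diagnosis == "BD"),
      g0 = quote(cohort == "CC" & diagnosis == "unaffected"),
      covariates = "sex", exclude_married_in = TRUE),
    FAM_BD_vs_CC_BD = list(
      g1 = quote(cohort == "FAM" & diagnosis == "BD"),
      g0 = quote(cohort == "CC" & diagnosis == "BD"),
      covariates = "sex", exclude_married_in = TRUE),
    FAM_unaffected_vs_CC_controls = list(
      g1 = quote(cohort == "FAM" & diagnosis == "unaffected"),
      g0 = quote(cohort == "CC" & diagnosis == "unaffected"),
      covariates = "sex", exclude_married_in = TRUE),
    FAM_MDD_vs_CC_controls = list(
      g1 = quote(cohort == "FAM" & diagnosis == "MDD"),
      g0 = quote(cohort == "CC" & diagnosis == "unaffected"),
      covariates = "sex", exclude_married_in = TRUE),
    FAM_BD_vs_FAM_unaffected = list(
      g1 = quote(cohort == "FAM" & diagnosis == "BD"),
      g0 = quote(cohort == "FAM" & diagnosis == "unaffected"),
      covariates = "sex", exclude_married_in = TRUE),
    married_in_vs_CC_controls = list(
      g1 = quote(cohort == "FAM" & married_in),
      g0 = quote(cohort == "CC" & diagnosis == "unaffected"),
      covariates = "sex", exclude_married_in = FALSE)
  )
}

#' Run the full PRS analysis on a simulated (or loaded) study
#'
#' Executes, in order: summary-statistic harmonisation and INFO filtering;
#' shared-disorder meta-analysis weights; a conditional (unique-liability)
#' BD score corrected for MDD; PRS profiles for the six score families
#' (BD, SCZ, MDD, Shared, BD-MDD, NEG); GRM on LD-pruned genotypes;
#' logistic mixed-model association for every configured contrast, score
#' family and threshold (one-sided, group 1 higher); the simulated-PRS
#' null calibration for the requested contrasts; and descriptive group
#' tables.  All outputs are written as TSV plus a JSON summary, stamped
#' with a config hash and the master seed.
#'
#' @param study A `sim_study` from [simulate_cohort()].
#' @param out_dir Output directory (created if needed).
#' @param thresholds p-value threshold grid.
#' @param contrasts Contrast list (see [default_contrasts()]).
#' @param n_sim Null-ensemble size per threshold (10000 at full scale;
#'   scale down for smoke tests).
#' @param calibrate_contrasts Names of contrasts to calibrate against the
#'   simulated-PRS null.
#' @param alpha Nominal significance level.
#' @param seed Master seed for the calibration ensemble.
#' @return Invisibly, a list with `associations`, `calibration`,
#'   `descriptives`, `profiles`, and the output paths.
#' @export
run_pipeline <- function(study, out_dir,
                         thresholds = prs_thresholds(),
                         contrasts = default_contrasts(),
                         n_sim = 1000L,
                         calibrate_contrasts = "FAM_BD_vs_CC_controls",
                         alpha = 0.05, seed = study$config$seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(...) cat(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), ...,
                            "\n", file = log_path, append = TRUE)
  stage <- function(name, expr) {
    logf("stage", name, "start")
    r <- tryCatch(expr, error = function(e)
      stop_famprs("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    logf("stage", name, "done")
    r
  }
  ss <- study$sumstats
  cfg <- study$config

  filtered <- stage("harmonise", lapply(ss, filter_info, lo = 0.6))
  shared <- stage("shared_meta",
                  shared_meta_stats(filtered$BD, filtered$SCZ, filtered$MDD))
  gwis_bd_mdd <- stage("gwis", {
    t9 <- filter_info(ss$BD, 0.9, 1.1)
    c9 <- filter_info(ss$MDD, 0.9, 1.1)
    # synthetic world has no LD: heritability/coheritability estimated with
    # the intercept constrained to 1 on empirical LD scores
    lds <- compute_ld_scores(study$panel, window = 25L)
    h2c <- ldsc_h2(c9, lds, N = cfg$gwas_n["MDD"], fixed_intercept = TRUE)
    coh <- ldsc_coherit(t9, c9, lds, N1 = cfg$gwas_n["BD"],
                        N2 = cfg$gwas_n["MDD"], fixed_intercept = TRUE)
    gwis_correct(t9, c9, h2_cov = max(h2c$h2, 1e-3), rho_g = coh$rho_g)
  })
  score_stats <- list(BD = filtered$BD, SCZ = filtered$SCZ,
                      MDD = filtered$MDD, Shared = shared,
                      `BD-MDD` = gwis_bd_mdd, NEG = filtered$NEG)

  profiles <- stage("prs", {
    pr <- lapply(names(score_stats), function(k)
      prs_profile(study$panel, score_stats[[k]], score_type = k,
                  thresholds = thresholds))
    do.call(rbind, pr)
  })
  write_prs_profile(profiles, file.path(out_dir, "prs_profiles.tsv"))

  K <- stage("grm", compute_grm(prune_ld(study$panel)))
  cohort <- study$cohort

  assoc <- stage("association", {
    rows <- list()
    for (cn in names(contrasts)) {
      cs <- contrasts[[cn]]
      in1 <- eval(cs$g1, cohort); in0 <- eval(cs$g0, cohort)
      if (cs$exclude_married_in) {
        in1 <- in1 & !cohort$married_in
        in0 <- in0 & !cohort$married_in
      }
      sel <- in1 | in0
      if (!any(in1) || !any(in0)) next
      ids <- cohort$iid[sel]
      y <- as.integer(in1[sel])
      covs <- cohort[sel, cs$covariates, drop = FALSE]
      Ks <- K[ids, ids]
      for (k in names(score_stats)) {
        sub <- profiles[profiles$score_type == k &
                          profiles$subject_id %in% ids, , drop = FALSE]
        for (thr in unique(sub$threshold)) {
          raw <- sub$raw[sub$threshold == thr][
            match(ids, sub$subject_id[sub$threshold == thr])]
          if (sd(raw) == 0) next
          z <- zstandardize(raw)  # standardised over exactly this sample
          fit <- tryCatch(
            fit_logistic_mixed(y, z, covariates = covs, K = Ks),
            error = function(e) NULL)
          if (is.null(fit)) next
          rows[[length(rows) + 1L]] <- data.frame(
            contrast = cn, score_type = k, threshold = thr,
            or = fit$or, ci_low = fit$ci[1], ci_high = fit$ci[2],
            p_one_sided = fit$p_one, sigma2 = fit$sigma2,
            converged = fit$converged, n = fit$n,
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
  data.table::fwrite(assoc, file.path(out_dir, "associations.tsv"),
                     sep = "\t")

  calib <- stage("calibration", {
    pool <- unlist(lapply(filtered[c("BD", "SCZ", "MDD")],
                          function(s) abs(s$BETA)))
    bd_counts <- with(profiles[profiles$score_type == "BD", ],
                      tapply(n_snps, threshold, max))
    out <- list()
    for (cn in intersect(calibrate_contrasts, names(contrasts))) {
      cs <- contrasts[[cn]]
      in1 <- eval(cs$g1, cohort); in0 <- eval(cs$g0, cohort)
      if (cs$exclude_married_in) {
        in1 <- in1 & !cohort$married_in
        in0 <- in0 & !cohort$married_in
      }
      sel <- in1 | in0
      ids <- cohort$iid[sel]
      y <- as.integer(in1[sel])
      covs <- build_design(NULL, cohort[sel, cs$covariates, drop = FALSE],
                           n = sum(sel))[, -1, drop = FALSE]
      Ks <- K[ids, ids]
      sub_panel <- subset_panel(study$panel,
                                subjects = match(ids,
                                                 rownames(study$panel$dosage)))
      ens <- draw_null_prs(sub_panel, bd_counts, pool, n_sim = n_sim,
                           seed = substream_seed(seed, paste0("null_", cn)))
      simp <- null_assoc_scan(ens, y, covariates = covs, K = Ks)
      thr <- choose_threshold(simp)
      for (k in c("BD", "SCZ", "MDD", "Shared")) {
        sub <- profiles[profiles$score_type == k &
                          profiles$threshold == thr, , drop = FALSE]
        raw <- sub$raw[match(ids, sub$subject_id)]
        if (!length(raw) || anyNA(raw) || sd(raw) == 0) next
        S <- matrix(zstandardize(raw), ncol = 1)
        p_dis <- null_assoc_scan(S, y, covariates = covs, K = Ks)[1, 1]
        cr <- calibrate_contrast(p_dis, simp[, as.character(thr)],
                                 alpha = alpha / 16)
        out[[length(out) + 1L]] <- data.frame(
          group = cn, disorder_prs = k, min_pprs = thr, n_success = cr$k,
          prob = cr$estimate, ci_low = cr$ci[1], ci_high = cr$ci[2],
          significant = cr$significant, stringsAsFactors = FALSE)
      }
    }
    if (length(out)) do.call(rbind, out) else NULL
  })
  if (!is.null(calib))
    data.table::fwrite(calib, file.path(out_dir, "calibration.tsv"),
                       sep = "\t")

  desc <- stage("descriptives", group_comparison_table(cohort))
  data.table::fwrite(desc, file.path(out_dir, "descriptives.tsv"),
                     sep = "\t")

  summary <- list(
    config_hash = config_hash(cfg), seed = seed,
    n_subjects = nrow(cohort), n_variants = ncol(study$panel$dosage),
    bonferroni_60 = bonferroni(alpha, 10 * length(score_stats)),
    top_associations = if (nrow(assoc)) {
      idx <- order(assoc$p_one_sided)[seq_len(min(5, nrow(assoc)))]
      assoc[idx, ]
    })
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(associations = assoc, calibration = calib,
                 descriptives = desc, profiles = profiles,
                 out_dir = out_dir))
}

#' Descriptive group comparisons (diagnosis-group table)
#'
#' Per diagnosis group and cohort: n, percent female, median/MAD of
#' interview and onset age with missing counts; pairwise sex chi-squared
#' and age Mann-Whitney tests between consecutive groups, Bonferroni
#' adjusted across the comparison family.
#'
#' @param cohort A `pedigree_cohort`.
#' @return data.frame, one row per group x statistic.
#' @export
group_comparison_table <- function(cohort) {
  grp <- interaction(cohort$cohort, cohort$diagnosis, drop = TRUE)
  levels_ <- levels(grp)
  rows <- lapply(levels_, function(g) {
    s <- cohort[grp == g, , drop = FALSE]
    mm_age <- median_mad(s$age_interview)
    ons <- if (any(!is.na(s$age_onset))) median_mad(s$age_onset)
    else list(median = NA, mad = NA, missing = nrow(s))
    data.frame(group = g, n = nrow(s),
               pct_female = percent_summary(sum(s$sex == 2), nrow(s)),
               age_median = mm_age$median, age_mad = mm_age$mad,
               onset_median = ons$median, onset_mad = ons$mad,
               onset_missing = ons$missing, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  pairs <- if (length(levels_) > 1)
    utils::combn(levels_, 2, simplify = FALSE) else list()
  m <- max(length(pairs), 1L)
  tests <- lapply(pairs, function(pr) {
    a <- cohort[grp == pr[1], ]; b <- cohort[grp == pr[2], ]
    mw <- mann_whitney(a$age_interview, b$age_interview)
    sx <- tryCatch(
      chi_squared(rbind(table(factor(a$sex, 1:2)),
                        table(factor(b$sex, 1:2)))),
      error = function(e) list(statistic = NA, p = NA))
    data.frame(group = paste(pr, collapse = " vs "), n = NA,
               pct_female = NA, age_median = NA, age_mad = NA,
               onset_median = NA, onset_mad = NA, onset_missing = NA,
               age_p = mw$p, age_p_adj = min(1, mw$p * m),
               sex_p = sx$p, sex_p_adj = min(1, sx$p * m),
               stringsAsFactors = FALSE)
  })
  tab$age_p <- tab$age_p_adj <- tab$sex_p <- tab$sex_p_adj <- NA_real_
  rbind(tab, do.call(rbind, tests))
}

config_hash <- function(cfg) {
  s <- paste(deparse(cfg[sort(names(cfg))]), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}
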