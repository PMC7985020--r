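#' Simulate a full study: multiplex families, case/control sample, GWAS
#'
#' Orchestrates the generator end-to-end: a true-effect panel; `n_families`
#' multiplex families (families are redrawn until they satisfy the
#' BD-case ascertainment rule, emulating clinic-based recruitment);
#' an unrelated BD case/control cohort drawn by rejection sampling from the
#' same population; and simulated training-GWAS summary statistics for each
#' configured disorder.
#'
#' @param config A [sim_config()].
#' @param seed Master seed (defaults to the config seed).
#' @param founder_enrichment Upper quantile of the true BD genetic score
#'   the founding couple's index member is drawn from (0 disables; the
#'   default 0.05 emulates recruitment through an affected proband line).
#' @param max_family_draws Cap on candidate families per accepted family.
#' @return list of class `sim_study`: `panel` (all subjects), `cohort`
#'   (a `pedigree_cohort` covering FAM and CC subjects), `sumstats`
#'   (named list of `summary_stats`), `effect_panel`, `config`.
#' @export
simulate_cohort <- function(config, seed = config$seed,
                            founder_enrichment = 0.05,
                            max_family_draws = 200L) {
  ep <- make_effect_panel(config, seed = seed)

  panels <- list(); peds <- list()
  kept <- 0L; tries <- 0L
  while (kept < config$n_families) {
    tries <- tries + 1L
    if (tries > max_family_draws * config$n_families)
      stop_famprs("multiplex ascertainment failed: too many rejected ",
                  "families; lower min_affected_for_multiplex or raise h2")
    fid <- sprintf("F%03d", kept + 1L)
    fam <- simulate_family(config, ep, fid,
                           seed = substream_seed(seed, paste0("fam", tries)),
                           founder_enrichment = founder_enrichment)
    ph <- assign_phenotypes(fam$panel, ep, config,
                            seed = substream_seed(seed, paste0("ph", tries)),
                            pedigree = fam$pedigree, cohort = "FAM")
    if (sum(ph$diagnosis == "BD") >= config$min_affected_for_multiplex) {
      kept <- kept + 1L
      panels[[kept]] <- fam$panel
      peds[[kept]] <- ph
    }
  }
  fam_panel <- Reduce(bind_panels, panels)
  fam_cohort <- do.call(rbind, lapply(peds, as.data.frame))
  L <- do.call(rbind, lapply(peds, attr, "liability"))
  G <- do.call(rbind, lapply(peds, attr, "gscore"))

  cc <- simulate_cc(config, ep, seed)
  panel <- bind_panels(fam_panel, cc$panel)
  cohort <- rbind(fam_cohort, as.data.frame(cc$cohort))
  attr(cohort, "liability") <- rbind(L, attr(cc$cohort, "liability"))
  attr(cohort, "gscore") <- rbind(G, attr(cc$cohort, "gscore"))
  class(cohort) <- c("pedigree_cohort", "data.frame")

  sumstats <- lapply(setNames(config$disorders, config$disorders),
                     function(d)
                       simulate_sumstats(ep, d, config$gwas_n[d],
                                         seed = substream_seed(seed, d)))
  structure(list(panel = panel, cohort = cohort, sumstats = sumstats,
                 effect_panel = ep, config = config,
                 families_tried = tries),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  tb <- table(x$cohort$cohort, x$cohort$diagnosis)
  cat("sim_study:", nrow(x$panel$dosage), "subjects,",
      ncol(x$panel$dosage), "variants\n")
  print(tb)
  invisible(x)
}

# Unrelated case/control sample: chunked rejection sampling until the BD
# case and screened-control quotas are met.
simulate_cc <- function(config, effect_panel, seed) {
  need_case <- config$n_cc_cases
  need_ctrl <- config$n_cc_controls
  chunk <- max(200L, min(5000L,
                         ceiling(need_case / max(config$prevalence["BD"], 1e-3))))
  got <- list(); li <- list(); gi <- list()
  n_case <- 0L; n_ctrl <- 0L; it <- 0L
  while ((n_case < need_case || n_ctrl < need_ctrl) && it < 400L) {
    it <- it + 1L
    pnl <- simulate_founders(chunk, effect_panel,
                             seed = substream_seed(seed, paste0("cc", it)),
                             ids = sprintf("CC%02d_%05d", it, seq_len(chunk)))
    ph <- assign_phenotypes(pnl, effect_panel, config,
                            seed = substream_seed(seed, paste0("ccph", it)),
                            cohort = "CC")
    is_case <- ph$diagnosis == "BD"
    is_ctrl <- ph$diagnosis == "unaffected"
    take_case <- which(is_case)[seq_len(min(sum(is_case),
                                            need_case - n_case))]
    take_ctrl <- which(is_ctrl)[seq_len(min(sum(is_ctrl),
                                            need_ctrl - n_ctrl))]
    take <- c(take_case, take_ctrl)
    if (length(take)) {
      got[[length(got) + 1L]] <- subset_panel(pnl, subjects = take)
      sub <- ph[take, , drop = FALSE]
      li[[length(li) + 1L]] <- attr(ph, "liability")[take, , drop = FALSE]
      gi[[length(gi) + 1L]] <- attr(ph, "gscore")[take, , drop = FALSE]
      got[[length(got)]]$pheno <- sub
      n_case <- n_case + length(take_case)
      n_ctrl <- n_ctrl + length(take_ctrl)
    }
  }
  if (n_case < need_case || n_ctrl < need_ctrl)
    stop_famprs("case/control rejection sampling did not reach its quota")
  panel <- Reduce(bind_panels, lapply(got, function(g)
    dosage_panel(g$dosage, g$variants, h1 = g$h1, h2 = g$h2)))
  cohort <- do.call(rbind, lapply(got, function(g) as.data.frame(g$pheno)))
  attr(cohort, "liability") <- do.call(rbind, li)
  attr(cohort, "gscore") <- do.call(rbind, gi)
  class(cohort) <- c("pedigree_cohort", "data.frame")
  list(panel = panel, cohort = cohort)
}
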