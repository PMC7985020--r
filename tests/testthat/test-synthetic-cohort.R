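test_that("founder dosages follow the configured allele frequencies", {
  ep <- manual_effect_panel(c(0, 1, 0.5))
  pnl <- simulate_founders(2000L, ep, seed = 7L)
  expect_true(all(pnl$dosage[, 1] == 0))
  expect_true(all(pnl$dosage[, 2] == 2))
  se <- sqrt(0.5 / 2000)
  expect_lt(abs(mean(pnl$dosage[, 3]) - 1), 4 * se)
  expect_true(all(pnl$dosage %in% 0:2))
  expect_equal(pnl$dosage, pnl$h1 + pnl$h2, ignore_attr = TRUE)
})

test_that("non-finite MAF is rejected", {
  ep <- manual_effect_panel(c(0.2, NaN))
  expect_error(simulate_founders(10L, ep, seed = 1L), "non-finite")
})

test_that("gene dropping obeys Mendelian constraints", {
  ep <- manual_effect_panel(c(0.5, 0.5))
  ped <- data.frame(fid = "F1", iid = c("p", "q", "kid"),
                    pat = c("0", "0", "p"), mat = c("0", "0", "q"),
                    sex = c(1L, 2L, 1L), generation = c(1L, 1L, 2L),
                    married_in = FALSE, stringsAsFactors = FALSE)
  founders <- dosage_panel(
    rbind(p = c(0, 2), q = c(0, 0)), ep[1:6],
    h1 = rbind(p = c(0L, 1L), q = c(0L, 0L)),
    h2 = rbind(p = c(0L, 1L), q = c(0L, 0L)))
  out <- gene_drop(ped, founders, seed = 3L)
  expect_equal(unname(out$dosage["kid", ]), c(0, 1))
})

test_that("heterozygous transmissions are fair", {
  # one het parent, many children: transmission frequency ~ 1/2
  n_kids <- 10000L
  ep <- manual_effect_panel(0.5)
  ped <- data.frame(fid = "F1",
                    iid = c("p", "q", paste0("k", seq_len(n_kids))),
                    pat = c("0", "0", rep("p", n_kids)),
                    mat = c("0", "0", rep("q", n_kids)),
                    sex = 1L, generation = c(1L, 1L, rep(2L, n_kids)),
                    married_in = FALSE, stringsAsFactors = FALSE)
  founders <- dosage_panel(rbind(p = 1, q = 0), ep[1:6],
                           h1 = rbind(p = 1L, q = 0L),
                           h2 = rbind(p = 0L, q = 0L))
  out <- gene_drop(ped, founders, seed = 11L)
  freq <- mean(out$dosage[-(1:2), 1])
  expect_lt(abs(freq - 0.5), 4 * sqrt(0.25 / n_kids))
})

test_that("gene drop names the subject with a missing parent", {
  ep <- manual_effect_panel(0.5)
  ped <- data.frame(fid = "F1", iid = c("p", "kid"),
                    pat = c("0", "p"), mat = c("0", "ghost"),
                    sex = 1L, generation = c(1L, 2L), married_in = FALSE,
                    stringsAsFactors = FALSE)
  founders <- simulate_founders(1L, ep, seed = 1L, ids = "p")
  expect_error(gene_drop(ped, founders, seed = 1L), "kid")
})

test_that("liability threshold diagnosis is deterministic at h2 = 1", {
  cfg <- sim_config(n_variants = 40L,
                    h2 = c(BD = 1, SCZ = 1, MDD = 1, NEG = 1),
                    prevalence = c(BD = 0.3, SCZ = 0.01, MDD = 0.3,
                                   NEG = 0.05),
                    seed = 5L)
  ep <- make_effect_panel(cfg)
  pnl <- simulate_founders(500L, ep, seed = 5L)
  ph <- assign_phenotypes(pnl, ep, cfg, seed = 6L)
  G <- true_genetic_scores(pnl, ep, cfg$h2)
  expect_identical(unname(ph$aff_BD), unname(G[, "BD"] > qnorm(0.7)))
  # BD takes precedence over MDD
  both <- ph$aff_BD & ph$aff_MDD
  expect_true(all(ph$diagnosis[both] == "BD"))
  expect_true(all(ph$diagnosis[!ph$aff_BD & ph$aff_MDD] == "MDD"))
})

test_that("population BD prevalence is recovered in unrelated subjects", {
  cfg <- sim_config(n_variants = 60L,
                    prevalence = c(BD = 0.05, SCZ = 0.01, MDD = 0.15,
                                   NEG = 0.05),
                    seed = 8L)
  ep <- make_effect_panel(cfg)
  n <- 20000L
  pnl <- simulate_founders(n, ep, seed = 8L)
  ph <- assign_phenotypes(pnl, ep, cfg, seed = 9L)
  se <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(mean(ph$aff_BD) - 0.05), 4 * se)
})

test_that("multiplex ascertainment filters and enriches", {
  st <- small_study()
  fam <- st$cohort[st$cohort$cohort == "FAM", ]
  attr(fam, "gscore") <- attr(st$cohort, "gscore")[st$cohort$cohort == "FAM", ]
  class(fam) <- class(st$cohort)
  expect_identical(ascertain_multiplex(fam, 0), fam)
  asc <- ascertain_multiplex(fam, 2)
  n_bd <- tapply(asc$diagnosis == "BD", asc$fid, sum)
  expect_true(all(n_bd >= 2))
  expect_error(ascertain_multiplex(fam, -1), "min_affected")
  # a family with no BD case disappears
  none <- fam[fam$fid == fam$fid[1], ]
  none$diagnosis <- "unaffected"
  class(none) <- class(fam)
  expect_equal(nrow(ascertain_multiplex(none, 2)), 0)
})

test_that("ascertained multiplex families carry more true BD genetic risk", {
  # unascertained null families vs the enriched, ascertained study families
  cfg <- sim_config(n_variants = 150L, n_families = 6L, n_cc_cases = 5L,
                    n_cc_controls = 5L, min_affected_for_multiplex = 2L,
                    seed = 21L)
  ep <- make_effect_panel(cfg)
  asc_means <- un_means <- numeric(8)
  for (r in 1:8) {
    fam <- simulate_family(cfg, ep, sprintf("A%02d", r), seed = 100L + r,
                           founder_enrichment = 0)
    un_means[r] <- mean(true_genetic_scores(fam$panel, ep, cfg$h2)[, "BD"])
  }
  st <- simulate_cohort(sim_config(n_variants = 150L, n_families = 8L,
                                   n_cc_cases = 5L, n_cc_controls = 5L,
                                   min_affected_for_multiplex = 2L,
                                   seed = 22L))
  g <- attr(st$cohort, "gscore")[st$cohort$cohort == "FAM", "BD"]
  fidx <- st$cohort$fid[st$cohort$cohort == "FAM"]
  asc_means <- tapply(g, fidx, mean)
  expect_gt(mean(asc_means), mean(un_means))
})

test_that("assortative mating induces the configured spouse correlation", {
  cfg <- sim_config(n_variants = 150L, generations_per_family = 2L,
                    children_per_couple = 2,
                    assortative_mating_strength = 0.7, seed = 30L)
  ep <- make_effect_panel(cfg)
  s1 <- s2 <- numeric(0)
  for (r in 1:60) {
    fam <- simulate_family(cfg, ep, sprintf("M%02d", r), seed = 300L + r)
    g <- true_genetic_scores(fam$panel, ep, cfg$h2)[, "BD"]
    s1 <- c(s1, g[fam$pedigree$iid[1]])
    s2 <- c(s2, g[fam$pedigree$iid[2]])
  }
  expect_gt(cor(s1, s2), 0.3)  # positive, substantial spouse correlation
})

test_that("simulated summary statistics match closed-form sampling theory", {
  ep0 <- manual_effect_panel(rep(0.5, 10000))
  ss <- simulate_sumstats(ep0, "BD", gwas_n = 20000, seed = 2L)
  expect_equal(unique(ss$SE), 1 / sqrt(2 * 0.25 * 20000))
  # SE halves when N quadruples
  ss4 <- simulate_sumstats(ep0, "BD", gwas_n = 80000, seed = 2L)
  expect_equal(ss4$SE, ss$SE / 2)
  # null effects: uniform p-values
  frac <- mean(ss$P < 0.05)
  expect_lt(abs(frac - 0.05), 4 * sqrt(0.05 * 0.95 / 10000))
  expect_true(all(ss$INFO > 0.4 & ss$INFO <= 1.1))
})

test_that("monomorphic variants are flagged with missing statistics", {
  ep <- manual_effect_panel(c(0, 0.3))
  ss <- simulate_sumstats(ep, "BD", gwas_n = 1000, seed = 1L)
  expect_identical(ss$flag, c("monomorphic", ""))
  expect_true(is.na(ss$SE[1]) && is.na(ss$P[1]))
})

test_that("true cross-disorder effect correlation matches the config", {
  cfg <- sim_config(n_variants = 4000L, seed = 17L)
  ep <- make_effect_panel(cfg)
  u <- attr(ep, "u")
  r <- cor(u[, "BD"], u[, "SCZ"])
  se <- (1 - 0.6^2) / sqrt(4000)
  expect_lt(abs(r - 0.6), 4 * se)
  expect_lt(abs(cor(u[, "BD"], u[, "NEG"])), 4 / sqrt(4000))
})

test_that("one generation of gene dropping does not drift allele frequencies", {
  ep <- manual_effect_panel(runif(200, 0.1, 0.5))
  sp <- sib_pair_panel(150L, ep, seed = 44L)
  kids <- sp$panel$dosage[sp$pedigree$pat != "0", ]
  drift <- colMeans(kids) / 2 - ep$maf
  binom_se <- sqrt(ep$maf * (1 - ep$maf) / (2 * nrow(kids)))
  expect_lt(mean(abs(drift) > 4 * binom_se), 0.01)
})
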