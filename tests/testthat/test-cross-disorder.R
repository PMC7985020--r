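make_three <- function(beta_bd, beta_scz, beta_mdd, p_bd, p_scz, p_mdd) {
  list(bd = manual_stats(beta_bd, p = p_bd),
       scz = manual_stats(beta_scz, p = p_scz),
       mdd = manual_stats(beta_mdd, p = p_mdd))
}

test_that("shared-set selection enforces threshold and sign concordance", {
  s <- make_three(c(0.1, 0.1, 0.1), c(0.2, -0.2, 0.2), c(0.1, 0.1, 0.1),
                  p_bd = c(0.04, 0.04, 0.06), p_scz = c(0.01, 0.01, 0.01),
                  p_mdd = c(0.03, 0.03, 0.03))
  ids <- select_shared(s$bd, s$scz, s$mdd)
  expect_equal(ids, "snp00001")  # snp2 discordant, snp3 above threshold
  # order of inputs is irrelevant
  expect_setequal(select_shared(s$mdd, s$bd, s$scz), ids)
  # concordance is judged on the common orientation, pre-flipping
  flipped <- s$scz
  flipped$A1 <- "G"; flipped$A2 <- "A"; flipped$BETA <- -flipped$BETA
  expect_setequal(select_shared(s$bd, flipped, s$mdd), ids)
})

test_that("DerSimonian-Laird reproduces hand-computed oracles", {
  # homogeneous: tau2 = 0 and SE shrinks by sqrt(k)
  r <- random_effects_meta(c(0.2, 0.2, 0.2), c(0.1, 0.1, 0.1))
  expect_equal(r$beta, 0.2)
  expect_equal(r$tau2, 0)
  expect_equal(r$se, 0.1 / sqrt(3))
  # k = 2 heterogeneous fixture: Q = 8, tau2 = (8-1)/(200-100) = 0.07
  r2 <- random_effects_meta(c(0, 0.4), c(0.1, 0.1))
  expect_equal(r2$Q, 8)
  expect_equal(r2$tau2, 0.07)
  expect_equal(r2$beta, 0.2)
  # permutation invariance
  r3 <- random_effects_meta(c(0.4, 0), c(0.1, 0.1))
  expect_equal(r3$beta, r2$beta)
  expect_equal(r3$se, r2$se)
  expect_error(random_effects_meta(c(0.1, 0.2), c(0.1, -0.1)), "positive")
  expect_error(random_effects_meta(0.1, 0.1), "k >= 2")
})

test_that("random effects reduce to inverse-variance fixed effects at tau2 = 0", {
  b <- c(0.10, 0.12, 0.11)
  s <- c(0.05, 0.08, 0.06)
  r <- random_effects_meta(b, s)
  if (r$tau2 == 0) {
    w <- 1 / s^2
    expect_equal(r$beta, sum(w * b) / sum(w))
    expect_equal(r$se, 1 / sqrt(sum(w)))
  } else skip("fixture produced tau2 > 0")
})

test_that("shared meta statistics feed the scoring engine unchanged", {
  st <- small_study()
  sh <- shared_meta_stats(st$sumstats$BD, st$sumstats$SCZ, st$sumstats$MDD)
  expect_s3_class(sh, "summary_stats")
  expect_true(all(sh$P <= 1 & sh$P > 0))
  expect_true(all(sh$SE > 0))
  ids <- select_shared(st$sumstats$BD, st$sumstats$SCZ, st$sumstats$MDD)
  expect_setequal(sh$SNP, ids)
  bd05 <- st$sumstats$BD$SNP[st$sumstats$BD$P < 0.05]
  expect_true(all(sh$SNP %in% bd05))
  prof <- prs_profile(st$panel, sh, score_type = "Shared",
                      thresholds = c(0.05, 0.2))
  expect_true(all(prof$scaled >= 0 & prof$scaled <= 1))
})

test_that("LDSC recovers a noiseless linear relationship exactly", {
  m <- 200
  l <- seq(1, 20, length.out = m)
  chi2 <- 1 + 0.5 * l
  z <- sqrt(chi2) * rep(c(1, -1), length.out = m)
  ss <- manual_stats(beta = z * 0.01, se = rep(0.01, m))
  est <- ldsc_h2(ss, data.frame(SNP = ss$SNP, L2 = l), N = m, M = m)
  expect_equal(est$h2, 0.5, tolerance = 1e-9)
  expect_equal(est$intercept, 1, tolerance = 1e-9)
  # self-coheritability equals heritability on noiseless input
  co <- ldsc_coherit(ss, ss, data.frame(SNP = ss$SNP, L2 = l),
                     N1 = m, N2 = m, M = m)
  expect_equal(co$rho_g, est$h2, tolerance = 1e-6)
  expect_equal(co$rg, 1)
  expect_error(ldsc_h2(ss[1:5, ], data.frame(SNP = ss$SNP, L2 = l)),
               "10 variants")
})

test_that("LDSC slope is null for independent null traits", {
  slopes <- sapply(1:50, function(s) {
    sim <- simulate_ldsc_stats(m = 500, n = c(5000, 5000), h2 = c(0, 0),
                               rg = 0, seed = s)
    ldsc_coherit(sim$stats[[1]], sim$stats[[2]], sim$ld_scores,
                 N1 = 5000, N2 = 5000, M = 500)$rho_g
  })
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes)), 4 * se)
})

test_that("the conditional correction has its closed-form limits", {
  st <- small_study()
  bd <- filter_info(st$sumstats$BD, 0.9, 1.1)
  mdd <- filter_info(st$sumstats$MDD, 0.9, 1.1)
  # rho_g = 0: identity on shared variants
  g0 <- gwis_correct(bd, mdd, h2_cov = 0.1, rho_g = 0)
  common <- match(g0$SNP, bd$SNP)
  expect_equal(g0$BETA, bd$BETA[common])
  expect_equal(g0$P, bd$P[common])
  # b = 1 with identical effects: complete attenuation
  g1 <- gwis_correct(bd, bd, h2_cov = 0.2, rho_g = 0.2)
  expect_equal(attr(g1, "b"), 1)
  expect_true(all(abs(g1$BETA) < 1e-12))
  expect_error(gwis_correct(bd, mdd, h2_cov = 0, rho_g = 0.1), "h2_cov")
})

test_that("the correction decorrelates target from covariate effects", {
  # large panel, shared causal component between two disorders
  m <- 3000
  u_c <- rnorm(m, 0, sqrt(0.3 / m))   # covariate effects
  u_t <- 0.8 * u_c + rnorm(m, 0, sqrt(0.2 / m))  # target shares them
  maf <- runif(m, 0.1, 0.5)
  sc <- sqrt(2 * maf * (1 - maf))
  tgt <- manual_stats(u_t / sc, se = 1 / (sc * sqrt(50000)))
  cov <- manual_stats(u_c / sc, se = 1 / (sc * sqrt(50000)))
  h2_cov <- sum(u_c^2)
  rho_g <- sum(u_c * u_t)
  g <- gwis_correct(tgt, cov, h2_cov = h2_cov, rho_g = rho_g)
  r <- cor(g$BETA * sc, u_c)
  expect_lt(abs(r), 4 / sqrt(m))
})

test_that("a zero-correlation correction leaves threshold sets unchanged", {
  st <- small_study()
  bd <- filter_info(st$sumstats$BD, 0.9, 1.1)
  mdd <- filter_info(st$sumstats$MDD, 0.9, 1.1)
  g0 <- gwis_correct(bd, mdd, h2_cov = 0.1, rho_g = 0)
  bd_common <- bd[bd$SNP %in% g0$SNP, ]
  for (thr in c(1e-4, 0.01, 0.2))
    expect_setequal(select_by_threshold(g0, thr)$SNP,
                    select_by_threshold(bd_common, thr)$SNP)
})
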