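test_that("LD pruning drops exactly the redundant variants", {
  ep <- manual_effect_panel(rep(0.5, 3))
  base <- rbinom(400, 2, 0.5)
  d <- cbind(base, base, rbinom(400, 2, 0.5))
  colnames(d) <- ep$variant_id
  pnl <- dosage_panel(d, ep[1:6])
  pruned <- prune_ld(pnl, window = 3, step = 1, r2_max = 0.99)
  expect_equal(ncol(pruned$dosage), 2)
  expect_true("snp00002" %in% attr(pruned, "removed")$variant_id)
  # r2_max = 1 keeps everything polymorphic
  expect_equal(ncol(prune_ld(pnl, r2_max = 1)$dosage), 3)
  # monomorphic variants removed and logged
  d2 <- d; d2[, 2] <- 0
  pnl2 <- dosage_panel(d2, ep[1:6])
  pr2 <- prune_ld(pnl2, r2_max = 0.99)
  expect_true(any(attr(pr2, "removed")$reason == "monomorphic"))
})

test_that("pruned output never contains a pair above the r2 ceiling", {
  st <- small_study()
  pruned <- prune_ld(st$panel, window = 30, step = 5, r2_max = 0.5)
  Z <- scale(pruned$dosage)
  m <- ncol(Z)
  # exhaustive within-window post-check
  for (j in seq_len(m - 1)) {
    upto <- min(m, j + 29)
    r2 <- (crossprod(Z[, j], Z[, (j + 1):upto, drop = FALSE]) /
             (nrow(Z) - 1))^2
    expect_true(all(r2 <= 0.5 + 1e-12))
  }
  # independent simulated variants are mostly retained
  expect_gt(ncol(pruned$dosage) / ncol(st$panel$dosage), 0.9)
})

test_that("the GRM has the identity-by-state and ordering properties", {
  ep <- manual_effect_panel(runif(120, 0.2, 0.5))
  pnl <- simulate_founders(60L, ep, seed = 3L)
  d <- pnl$dosage
  d[2, ] <- d[1, ]  # duplicated subject
  pnl2 <- dosage_panel(d, pnl$variants)
  K <- compute_grm(pnl2, ridge = 0)
  expect_equal(K[1, 2], K[1, 1])
  expect_equal(K[1, 2], K[2, 2])
  # invariance to subject ordering
  perm <- sample(nrow(d))
  K2 <- compute_grm(subset_panel(pnl2, subjects = perm), ridge = 0)
  expect_equal(unclass(K2), unclass(K)[perm, perm], ignore_attr = TRUE)
  # unrelated subjects: off-diagonals centre on the exact small negative
  # value -1/(n-1) induced by sample-frequency centring
  K3 <- compute_grm(pnl, ridge = 0)
  off <- K3[upper.tri(K3)]
  n <- nrow(K3)
  expect_lt(abs(mean(off) + 1 / (n - 1)), 4 * sd(off) / sqrt(length(off)))
  expect_lt(mean(abs(off)), 3 / sqrt(ncol(pnl$dosage)))
  expect_error(compute_grm(dosage_panel(matrix(2, 5, 2),
                                        ep[1:2, 1:6])), "polymorphic")
})

test_that("parent-offspring genomic relatedness averages one half", {
  ep <- manual_effect_panel(runif(400, 0.1, 0.5))
  sp <- sib_pair_panel(120L, ep, seed = 9L)
  K <- compute_grm(sp$panel, ridge = 0)
  po <- mapply(function(kid, par) K[kid, par],
               sp$pedigree$iid[sp$pedigree$pat != "0"],
               sp$pedigree$pat[sp$pedigree$pat != "0"])
  expect_lt(abs(mean(po) - 0.5), 4 * sd(po) / sqrt(length(po)))
})

test_that("the logistic mixed model matches a GLM when sigma2 = 0", {
  set.seed(31)
  n <- 120
  x <- rnorm(n)
  sex <- sample(1:2, n, TRUE)
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x))
  K <- diag(n)
  f <- fit_logistic_mixed(y, x, covariates = data.frame(sex = sex), K = K,
                          sigma2 = 0)
  g <- glm(y ~ x + sex, family = binomial)
  expect_equal(f$beta, unname(coef(g)["x"]), tolerance = 1e-6)
  expect_equal(f$se, sqrt(vcov(g)["x", "x"]), tolerance = 1e-6)
  expect_equal(f$p_two, 2 * f$p_one, tolerance = 1e-12) # beta > 0 here
})

test_that("one-sided conventions and degenerate inputs behave", {
  # perfectly balanced design: estimate 0, one-sided p = 0.5
  y <- rep(c(0, 1), 10)
  x <- rep(c(-1, 1, 1, -1), 5)
  f <- fit_logistic_mixed(y, x, K = diag(20), sigma2 = 0)
  expect_equal(f$beta, 0, tolerance = 1e-10)
  expect_equal(f$p_one, 0.5, tolerance = 1e-8)
  expect_error(fit_logistic_mixed(rep(1, 10), rnorm(10), K = diag(10)),
               "constant")
  expect_error(fit_logistic_mixed(y, rep(1, 20), K = diag(20)),
               "rank")
  # CI brackets the OR
  set.seed(4)
  y2 <- rbinom(40, 1, 0.5)
  f2 <- fit_logistic_mixed(y2, rnorm(40), K = diag(40), sigma2 = 0)
  expect_true(f2$ci[1] < f2$or && f2$or < f2$ci[2])
})

test_that("the quantitative LMM collapses to OLS without random effects", {
  set.seed(77)
  n <- 80
  x <- rnorm(n)
  cov <- data.frame(age = rnorm(n, 50, 10))
  y <- 1 + 0.3 * x + 0.02 * cov$age + rnorm(n)
  f <- fit_lmm_quant(y, x, covariates = cov, K = diag(n),
                     fix = c(g = 0))
  o <- lm(y ~ x + age, data = cov)
  expect_equal(f$beta, unname(coef(o)["x"]), tolerance = 1e-6)
  expect_equal(f$se, sqrt(vcov(o)["x", "x"]), tolerance = 1e-6)
  # location invariance
  f2 <- fit_lmm_quant(y + 100, x, covariates = cov, K = diag(n),
                      fix = c(g = 0))
  expect_equal(f2$beta, f$beta, tolerance = 1e-8)
})

test_that("permutation p-values are deterministic and bounded", {
  set.seed(5)
  n <- 40
  x <- rnorm(n)
  y <- x + rnorm(n, 0, 0.1)  # overwhelming association
  f <- fit_lmm_quant(y, x, fid = rep(1:8, each = 5))
  p1 <- permutation_p(f, n_perm = 4, seed = 99)
  p2 <- permutation_p(f, n_perm = 4, seed = 99)
  expect_identical(p1, p2)
  expect_true(p1$lt)          # observed beats every permutation
  expect_equal(p1$k, 0L)
  # granularity: p = k / n_perm
  y3 <- rnorm(n)
  f3 <- fit_lmm_quant(y3, x, fid = rep(1:8, each = 5))
  p3 <- permutation_p(f3, n_perm = 25, seed = 1)
  expect_equal(p3$p_perm, p3$k / 25)
})

test_that("the cluster bootstrap is seeded and brackets the estimate", {
  set.seed(6)
  n <- 60
  fid <- rep(1:12, each = 5)
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(n, 0, 0.3)
  f <- fit_lmm_quant(y, x, fid = fid)
  b1 <- bootstrap_ci(f, n_boot = 120, seed = 3)
  b2 <- bootstrap_ci(f, n_boot = 120, seed = 3)
  expect_identical(b1$ci, b2$ci)
  expect_true(b1$ci[1] < f$beta && f$beta < b1$ci[2])
  # interval tightens as noise vanishes
  y0 <- 0.5 * x + rnorm(n, 0, 1e-4)
  f0 <- fit_lmm_quant(y0, x, fid = fid)
  b0 <- bootstrap_ci(f0, n_boot = 120, seed = 3)
  expect_lt(diff(b0$ci), diff(b1$ci))
  expect_lt(abs(mean(b0$ci) - 0.5), 0.01)
})

test_that("null generational trend stays null in the family LMM", {
  st <- small_study()
  fam <- st$cohort[st$cohort$cohort == "FAM" & !st$cohort$married_in, ]
  prof <- prs_profile(st$panel, filter_info(st$sumstats$BD, 0.6),
                      thresholds = 0.2)
  raw <- prof$raw[match(fam$iid, prof$subject_id)]
  K <- compute_grm(st$panel)[fam$iid, fam$iid]
  f <- fit_lmm_quant(zstandardize(raw), fam$generation, K = K,
                     fid = fam$fid)
  # no generational trend was simulated; just check the machinery runs and
  # reports a sane two-sided p
  expect_true(f$p_two > 0 && f$p_two <= 1)
  expect_true(f$converged)
})
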