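# REML core shared by the quantitative LMM and the fast null scan.
# Estimates variance components of y = X b + u + v + e with
# u ~ N(0, s_g K), v ~ N(0, s_v ZZ'), e ~ N(0, s_e I) by derivative-free
# search on log-variances; returns components, V and the GLS fit.
reml_fit <- function(y, X, K = NULL, Z = NULL, fix = NULL) {
  n <- length(y)
  comp <- c(if (!is.null(K)) "g", if (!is.null(Z)) "v")
  fixed <- setNames(rep(0, length(comp)), comp)
  if (!is.null(fix)) fixed[intersect(names(fix), comp)] <-
      fix[intersect(names(fix), comp)]
  est <- setdiff(comp, names(fix))
  vy <- max(var(y), 1e-12)

  make_V <- function(s) {
    V <- diag(s[["e"]], n)
    if (!is.null(K)) V <- V + s[["g"]] * K
    if (!is.null(Z)) V <- V + s[["v"]] * tcrossprod(Z)
    V
  }
  crit <- function(s) {
    ch <- tryCatch(chol(make_V(s)), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    Xi <- backsolve(ch, X, transpose = TRUE)
    yi <- backsolve(ch, y, transpose = TRUE)
    XtVX <- crossprod(Xi)
    b <- solve(XtVX, crossprod(Xi, yi))
    ri <- yi - Xi %*% b
    as.numeric(0.5 * (2 * sum(log(diag(ch))) +
                        determinant(XtVX, logarithm = TRUE)$modulus +
                        sum(ri^2)))
  }
  unpack <- function(par) {
    s <- c(fixed, e = 0)
    if (length(est)) s[est] <- exp(par[seq_along(est)])
    s[["e"]] <- exp(par[length(par)])
    s
  }
  par0 <- log(rep(vy / (length(est) + 1), length(est) + 1))
  opt <- if (length(par0) > 1) {
    optim(par0, function(p) crit(unpack(p)), method = "Nelder-Mead",
          control = list(maxit = 2000, reltol = 1e-10))
  } else {
    o <- optimize(function(p) crit(unpack(p)),
                  interval = log(vy) + c(-12, 6), tol = 1e-9)
    list(par = o$minimum, value = o$objective, convergence = 0L)
  }
  s <- unpack(opt$par)
  V <- make_V(s)
  ch <- chol(V)
  Xi <- backsolve(ch, X, transpose = TRUE)
  yi <- backsolve(ch, y, transpose = TRUE)
  XtVX <- crossprod(Xi)
  b <- solve(XtVX, crossprod(Xi, yi))
  list(varcomp = s, V = V, chol = ch, beta = as.numeric(b),
       cov = solve(XtVX), converged = opt$convergence == 0L)
}

#' Linear mixed model for quantitative traits with kinship
#'
#' Fits `y = alpha + beta x + gamma' c + u + v + e` with
#' `u ~ N(0, sigma2_g K)`, an optional i.i.d. random intercept `v` on the
#' groups of `extra_re` (e.g., married-in status within families), and an
#' independent residual.  Variance components are estimated by REML with a
#' derivative-free Nelder-Mead search on log-variances; fixed effects by
#' GLS at the optimum, with Wald inference on the focal coefficient.
#' With the non-residual components fixed at zero the fit coincides with
#' ordinary least squares.
#'
#' @param y Quantitative outcome.
#' @param x Focal predictor.
#' @param covariates Optional fixed-effect covariates (matrix/data.frame).
#' @param K GRM (NULL to omit the genetic component).
#' @param extra_re Optional grouping for a second random intercept.
#' @param fix Optional named numeric fixing components, e.g. `c(g = 0)`.
#' @param fid Optional family ids (enables the cluster bootstrap).
#' @return list of class `quant_result`: `beta`, `se`, `z`, `p_one`,
#'   `p_two`, `varcomp`, `converged`, and the model frame used by
#'   [permutation_p()] and [bootstrap_ci()].
#' @export
fit_lmm_quant <- function(y, x, covariates = NULL, K = NULL,
                          extra_re = NULL, fix = NULL, fid = NULL) {
  X <- build_design(x, covariates, n = length(y))
  if (qr(X)$rank < ncol(X)) stop_famprs("model matrix is rank deficient")
  Z <- if (!is.null(extra_re)) model.matrix(~ factor(extra_re) - 1)
  fit <- reml_fit(y, X, K = K, Z = Z, fix = fix)
  beta <- fit$beta[2L]
  se <- sqrt(fit$cov[2L, 2L])
  zstat <- beta / se
  structure(list(beta = beta, se = se, z = zstat,
                 p_one = 1 - pnorm(zstat), p_two = 2 * pnorm(-abs(zstat)),
                 varcomp = fit$varcomp, converged = fit$converged,
                 coefficients = fit$beta,
                 model = list(y = y, x = x, covariates = covariates,
                              K = K, extra_re = extra_re, fix = fix,
                              fid = fid)),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("LMM: beta = %.4f (SE %.4f), two-sided p = %.3g\n",
              x$beta, x$se, x$p_two))
  cat("variance components:",
      paste(names(x$varcomp), signif(unlist(x$varcomp), 3),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Permutation p-value for a fitted mixed model
#'
#' Recomputes the model under `n_perm` random permutations of the
#' phenotype vector (covariates, kinship and random-effect structure held
#' fixed) and reports the fraction of permutations whose p-value is at
#' most the observed one.  A count of zero is reported with the `lt` flag
#' (p below the 1/n_perm granularity).  Failed permutation fits are
#' redrawn, capped at `2 * n_perm` total attempts.
#'
#' @param fit A `quant_result` from [fit_lmm_quant()].
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param within Optional grouping; permute within groups when given.
#' @return list: `p_perm`, `k`, `n_perm`, `lt`.
#' @export
permutation_p <- function(fit, n_perm = 10000L, seed = 1L, within = NULL) {
  if (n_perm < 1) stop_famprs("n_perm must be >= 1")
  m <- fit$model
  p_obs <- fit$p_two
  k <- 0L; done <- 0L
  with_substream(seed, "permutation", {
    attempts <- 0L
    while (done < n_perm && attempts < 2L * n_perm) {
      attempts <- attempts + 1L
      idx <- if (is.null(within)) sample(length(m$y)) else {
        out <- seq_along(m$y)
        for (g in unique(within)) {
          gi <- which(within == g)
          out[gi] <- gi[sample(length(gi))]
        }
        out
      }
      pf <- tryCatch(
        fit_lmm_quant(m$y[idx], m$x, covariates = m$covariates, K = m$K,
                      extra_re = m$extra_re, fix = m$fix),
        error = function(e) NULL)
      if (is.null(pf)) next
      done <- done + 1L
      if (pf$p_two <= p_obs) k <- k + 1L
    }
  })
  if (done < n_perm)
    warning("only ", done, " of ", n_perm, " permutations converged")
  list(p_perm = k / max(done, 1L), k = k, n_perm = done, lt = k == 0L)
}

#' Cluster (family) bootstrap confidence interval
#'
#' Resamples whole families with replacement, refits the model on each
#' resample (each drawn family becomes an independent cluster; kinship is
#' rebuilt block-diagonally from the original family blocks) and returns
#' the percentile interval of the focal coefficient.  Resamples with a
#' constant outcome or predictor are redrawn, capped at `2 * n_boot`.
#'
#' @param fit A `quant_result` whose model carries `fid`.
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return list: `ci` (length 2), `estimates`.
#' @export
bootstrap_ci <- function(fit, n_boot = 1000L, seed = 1L, level = 0.95) {
  if (n_boot < 100) stop_famprs("n_boot must be >= 100")
  m <- fit$model
  if (is.null(m$fid)) stop_famprs("model was fitted without family ids")
  fams <- unique(m$fid)
  idx_by_fam <- split(seq_along(m$y), m$fid)
  est <- numeric(0)
  with_substream(seed, "bootstrap", {
    attempts <- 0L
    while (length(est) < n_boot && attempts < 2L * n_boot) {
      attempts <- attempts + 1L
      draw <- sample(fams, length(fams), replace = TRUE)
      pieces <- idx_by_fam[as.character(draw)]
      idx <- unlist(pieces, use.names = FALSE)
      if (var(m$y[idx]) == 0 || var(m$x[idx]) == 0) next
      Kb <- if (!is.null(m$K))
        block_diag(lapply(pieces, function(i) m$K[i, i, drop = FALSE]))
      bf <- tryCatch(
        fit_lmm_quant(m$y[idx], m$x[idx],
                      covariates = if (!is.null(m$covariates))
                        m$covariates[idx, , drop = FALSE],
                      K = Kb,
                      extra_re = if (!is.null(m$extra_re)) m$extra_re[idx],
                      fix = m$fix),
        error = function(e) NULL)
      if (!is.null(bf)) est <- c(est, bf$beta)
    }
  })
  a <- (1 - level) / 2
  list(ci = unname(quantile(est, c(a, 1 - a))), estimates = est)
}

block_diag <- function(blocks) {
  sizes <- vapply(blocks, nrow, 1L)
  M <- matrix(0, sum(sizes), sum(sizes))
  at <- 0L
  for (b in blocks) {
    i <- at + seq_len(nrow(b))
    M[i, i] <- b
    at <- at + nrow(b)
  }
  M
}
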