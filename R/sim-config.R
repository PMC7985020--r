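#' Simulation configuration for the synthetic multiplex-family world
#'
#' Bundles every quantity the synthetic-cohort generator takes as given:
#' variant panel size and allele-frequency range, pedigree structure,
#' case/control sample sizes, per-disorder liability-scale heritabilities,
#' the cross-disorder genetic correlation matrix, population prevalences,
#' training-GWAS sample sizes, the multiplex ascertainment rule and the
#' assortative-mating strength.
#'
#' The four disorders are `BD`, `SCZ`, `MDD` and `NEG`; `NEG` is a
#' genetically uncorrelated negative control standing in for a
#' non-psychiatric trait.  Default heritabilities and prevalences are
#' typical SNP-based values for these disorders; the genetic correlations
#' default to the well-replicated BD/SCZ/MDD triangle with `NEG`
#' uncorrelated.
#'
#' @param n_variants Number of simulated variants.
#' @param maf_range Length-2 numeric, minor-allele-frequency range in (0,1).
#' @param n_families Number of multiplex families to ascertain.
#' @param generations_per_family Pedigree depth (founding couple = 1).
#' @param children_per_couple Mean of the (zero-truncated) Poisson number
#'   of children per couple.
#' @param n_cc_cases,n_cc_controls Unrelated case/control sample sizes.
#' @param h2 Named numeric, narrow-sense liability heritability per disorder.
#' @param genetic_correlation Symmetric PSD matrix with unit diagonal over
#'   the disorders of `h2`.
#' @param env_correlation Residual (environmental) liability correlation
#'   matrix; the identity by default (the free parameter of the model).
#' @param prevalence Named numeric, lifetime population prevalences.
#' @param gwas_n Named numeric, effective training-GWAS sample sizes.
#' @param min_affected_for_multiplex Minimum BD cases for a family to be
#'   retained as multiplex.
#' @param assortative_mating_strength Spouse correlation in [0,1) of true
#'   BD genetic scores; 0 is random mating.
#' @param prop_causal Proportion of variants carrying nonzero effects.
#' @param seed Master seed; all operations derive named substreams from it.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_variants = 2000L,
                       maf_range = c(0.05, 0.5),
                       n_families = 33L,
                       generations_per_family = 3L,
                       children_per_couple = 3,
                       n_cc_cases = 161L,
                       n_cc_controls = 277L,
                       h2 = c(BD = 0.20, SCZ = 0.24, MDD = 0.10, NEG = 0.10),
                       genetic_correlation = default_genetic_correlation(),
                       env_correlation = NULL,
                       prevalence = c(BD = 0.01, SCZ = 0.01, MDD = 0.15,
                                      NEG = 0.05),
                       gwas_n = c(BD = 50000, SCZ = 75000, MDD = 450000,
                                  NEG = 50000),
                       min_affected_for_multiplex = 2L,
                       assortative_mating_strength = 0,
                       prop_causal = 1,
                       seed = 1L) {
  disorders <- names(h2)
  if (is.null(disorders) || anyNA(disorders))
    stop_famprs("h2 must be a named vector of disorders")
  if (any(h2 < 0 | h2 > 1)) stop_famprs("h2 values must lie in [0,1]")
  if (any(prevalence <= 0 | prevalence >= 1))
    stop_famprs("prevalence values must lie in (0,1)")
  if (!setequal(names(prevalence), disorders) ||
      !setequal(names(gwas_n), disorders))
    stop_famprs("h2, prevalence and gwas_n must name the same disorders")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range >= 1) ||
      maf_range[1] > maf_range[2])
    stop_famprs("maf_range must be an increasing pair in (0,1)")
  if (assortative_mating_strength < 0 || assortative_mating_strength >= 1)
    stop_famprs("assortative_mating_strength must lie in [0,1)")
  check_corr <- function(m, what) {
    if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
      stop_famprs(what, " must be symmetric")
    if (any(abs(diag(m) - 1) > 1e-8))
      stop_famprs(what, " must have a unit diagonal")
    if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stop_famprs(what, " must be positive semi-definite")
    m
  }
  genetic_correlation <-
    check_corr(genetic_correlation[disorders, disorders], "genetic_correlation")
  if (is.null(env_correlation))
    env_correlation <- diag(length(disorders))
  dimnames(env_correlation) <- list(disorders, disorders)
  env_correlation <- check_corr(env_correlation, "env_correlation")
  if (min_affected_for_multiplex < 0)
    stop_famprs("min_affected_for_multiplex must be >= 0")

  structure(list(
    n_variants = as.integer(n_variants), maf_range = maf_range,
    n_families = as.integer(n_families),
    generations_per_family = as.integer(generations_per_family),
    children_per_couple = children_per_couple,
    n_cc_cases = as.integer(n_cc_cases),
    n_cc_controls = as.integer(n_cc_controls),
    h2 = h2, genetic_correlation = genetic_correlation,
    env_correlation = env_correlation,
    prevalence = prevalence, gwas_n = gwas_n,
    min_affected_for_multiplex = as.integer(min_affected_for_multiplex),
    assortative_mating_strength = assortative_mating_strength,
    prop_causal = prop_causal,
    disorders = disorders, seed = as.integer(seed)
  ), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_genetic_correlation <- function() {
  d <- c("BD", "SCZ", "MDD", "NEG")
  m <- diag(4)
  dimnames(m) <- list(d, d)
  m["BD", "SCZ"] <- m["SCZ", "BD"] <- 0.60
  m["BD", "MDD"] <- m["MDD", "BD"] <- 0.35
  m["SCZ", "MDD"] <- m["MDD", "SCZ"] <- 0.34
  m
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_variants, "variants,", x$n_families, "families,",
      x$n_cc_cases, "CC cases /", x$n_cc_controls, "CC controls\n")
  cat("disorders:", paste(x$disorders, collapse = ", "), "\n")
  invisible(x)
}

# Run an expression under a derived substream seed, restoring the caller's
# RNG state afterwards so simulator internals never perturb user code.
with_substream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(substream_seed(seed, stream))
  expr
}
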