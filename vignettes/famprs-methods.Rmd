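---
title: "famprs: methods, defaults and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{famprs: methods, defaults and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
the models, the defaults and why they are set where they are, what the
synthetic-data generator does and does not emulate, and where the design
was genuinely open.

## 1. Score construction

A polygenic risk score at training threshold `p_PRS` is the weighted dosage
sum over variants with training p-value strictly below the threshold.
Three conventions fix the scale:

* **Positive harmonisation** (`harmonize_positive`): any variant with a
  negative training effect has its alleles swapped, effect negated and
  frequency complemented, so all weights are risk-increasing and the score
  is a cumulative risk load.  P-values and |effect| are untouched; the
  operation is idempotent.
* **Relative risk-load scaling**: `scaled = raw / (2 Σ w_j)`.  The
  denominator is the unique normaliser for which the minimum (no risk
  alleles) maps to 0 and the maximum (homozygous for every risk allele)
  maps to 1 with non-negative weights.  When all weights are zero the
  scaled score is defined as 0.
* **Z-standardisation** is recomputed over *exactly* the subjects entering
  each model (sample SD, n−1), so per-SD odds ratios are comparable across
  score families and contrasts.  Subjects excluded from a contrast (for
  example married-in members) never influence its standardisation.

Missing dosages are mean-imputed from the analysis sample (2× the sample
allele frequency) and counted; the ten-threshold grid produces nested
variant sets, so raw scores are monotone in the threshold.

No LD clumping precedes thresholding: the scoring design works on
already-imputed panels and treats the threshold grid itself as the only
variant selection.  LD pruning exists solely for the relationship matrix.

## 2. Shared and disorder-specific statistics

The **shared score** takes variants with `p < 0.05` in all three disorder
GWAS whose effects point the same way *on a common allele orientation,
before positive flipping* (flipping first would make concordance vacuous),
then combines effects by DerSimonian–Laird random-effects meta-analysis.
DL was chosen because it is the method-of-moments default of standard
meta-analytic practice; the estimator is recorded in the output metadata,
and the result reduces to inverse-variance fixed effects when the
between-study variance hits zero.

The **conditional (unique-liability) statistics** implement the linear
special case of genome-wide inferred statistics: with covariate
heritability `h²_cov` and coheritability `ρ_g`,

```
b    = ρ_g / h²_cov
β*_j = β_target,j − b · β_cov,j
SE*  = sqrt(SE_target² + b² · SE_cov²)
```

assuming non-overlapping training samples (zero sampling covariance).  `b`
is exposed as an attribute for inspection because the scaling convention
(ρ_g vs r_g) is not recoverable from the descriptions this follows; the
implementation pins the conditional-regression coefficient, which is the
variance-scaled ρ_g form.  Inputs are expected INFO-filtered to
[0.9, 1.1] — the stricter band used for conditional statistics — while
standard scores use INFO ≥ 0.6.  Both filters are **boundary-inclusive**:
"below 0.6 removed" keeps exactly 0.6.

`h²` and `ρ_g` come from LD score regression: weighted least squares of
χ² on LD scores (slope `N·h²/M`) and of z-score products (slope
`√(N₁N₂)·ρ_g/M`), weights `1/max(l_j, 1)`, genetic correlation clamped to
[−1, 1].  Point estimates only — downstream use needs no standard errors.
A `fixed_intercept` switch constrains the intercepts to their
no-confounding values (1 and 0); the pipeline uses it because the default
synthetic world is in linkage equilibrium, where LD scores have no spread
and a free intercept is unidentified.  On real data the free intercept is
the safer default and remains so in the exported functions.

## 3. Mixed-model association

Binary contrasts use a logistic mixed model with a genetic relationship
matrix `K` as the random-effect covariance.  `K` is the
centred-standardised (GEMMA-style) kinship on LD-pruned dosages (defaults:
window 50 variants, step 5, drop r² > 0.5 — configurable, logged), with a
1e-6 diagonal ridge for numerical positive-definiteness.  Fitting is
penalised quasi-likelihood: iteratively reweighted GLS on the working
response inside, and the working-model REML criterion maximised over σ²
outside by a derivative-free Brent search on [0, 10] (the multi-component
linear model uses Nelder–Mead; both are simplex/derivative-free choices in
the spirit of the original fitting routine).  Wald inference uses the PQL
working-model covariance — the documented choice where a profiled
likelihood SE was the alternative — and σ² is reported for inspection.
With σ² = 0 the algorithm *is* logistic IRLS, which the tests exploit as
an oracle equivalence (tolerance 1e-6).

One-sided p-values follow a single convention: the group coded 1 is
hypothesised to have the higher score, H1: β > 0, `p = 1 − Φ(z)`; hence
`p_one = p_two/2` whenever the estimate points the hypothesised way.

Quantitative analyses (anticipation, age at onset) use a REML linear mixed
model with the kinship component plus an optional i.i.d. random intercept
(e.g. married-in status).  Confidence intervals come from a **cluster
bootstrap resampling whole families** — observations within a family are
not exchangeable, and the resampled kinship is rebuilt block-diagonally so
each drawn family is an independent cluster.  Permutation p-values permute
the phenotype vector across all subjects (10,000 at full scale), matching
the stated procedure even though unrestricted permutation breaks family
structure under the null; a within-family mode is available as an option.
Failed permutation fits are redrawn with a 2× attempt cap; a zero count is
reported as `p < 1/n_perm`.

## 4. Simulated-PRS null calibration

For a contrast, 10,000 random scores per threshold are drawn: variant sets
sampled uniformly without replacement with the *same SNP count as the BD
score* at that threshold, and weights resampled **with replacement** from
the pooled harmonised BD/SCZ/MDD effects (with-replacement keeps the
procedure independent of pool size; the source description does not state
it).  Because 100,000 logistic fits are impractical, the scan fixes the
REML variance components estimated once on the outcome-without-score model
and Wald-tests every simulated score by GLS — the fast
restricted-likelihood path; the test suite checks rank agreement between
this path and full logistic fits on a small ensemble.  The comparison
threshold is the one minimising the mean simulated p (ties broken toward
the more permissive threshold, logged), the success count uses
`p_sim ≤ p_disorder` (ties are successes), and the estimate gets an exact
Clopper–Pearson 95% CI with the reporting conventions: estimates to 4
decimals, CI bounds to 3, zero counts printed as `<1e-04`, significance
flagged against 0.05/16.

## 5. The synthetic world

The generator exists so that every stage above is exercised end-to-end by
code, not by downloads.  It emulates:

* **Effects**: per-variant standardised effects jointly normal across
  disorders, `Σu² = h²` per disorder, cross-disorder correlation as
  configured.  Defaults are field-typical SNP-based values — h² 0.20 (BD),
  0.24 (SCZ), 0.10 (MDD); r_g 0.60 (BD–SCZ), 0.35 (BD–MDD), 0.34
  (SCZ–MDD); prevalences 1%, 1%, 15% — plus an uncorrelated negative
  control ("NEG") standing in for a non-psychiatric score.
* **Pedigrees**: a founding couple, zero-truncated-Poisson offspring
  (mean 3 children per couple, chosen to give the ~12-member multiplex
  families typical of such cohorts over 3 generations), spouses marrying
  in, gene-dropped genotypes (fair Mendelian transmission, tested), and a
  liability-threshold phenotype `L = √h²·G + √(1−h²)·E` with BD taking
  diagnostic precedence over MDD (the DSM-style hierarchy implied by
  mutually exclusive diagnostic groups).  `G` is normalised by the
  *realised* effect norm so configured prevalences are met exactly for
  finite panels.
* **Ascertainment**: families are redrawn until they contain at least
  `min_affected_for_multiplex` BD cases; the founding couple's index
  member is drawn from the top 5% of true BD genetic score by default,
  emulating recruitment through an affected proband line and keeping
  rejection sampling tractable.  Environmental liability correlation
  across disorders is a free parameter (identity by default) because no
  value is asserted by the sources this design follows.
* **Assortative mating**: spouses are matched by rank to a noisy
  `r·z + √(1−r²)·ε` target on the true BD genetic score — strength 0 is
  random mating; the mechanism is a package choice since only the
  phenomenon, not a mechanism, is discussed in the literature this mirrors.
* **Training GWAS**: `β̂ = β_true + ε`, `SE = 1/√(2p(1−p)N)`, uniform INFO
  on (0.4, 1.1] to exercise filters; monomorphic variants are emitted
  flagged with missing statistics.
* **LD**: linkage equilibrium by default — threshold scoring does no
  clumping, so LE is the tractable default.  A block-exchangeable mode
  exists both at the genotype level (Gaussian-copula blocks, for pruning
  and empirical LD scores) and at the summary-statistic level
  (`simulate_ldsc_stats`, with analytic LD scores `1 + (B−1)r²`), the
  latter used for LDSC parameter-recovery tests because it is the
  estimator's exact generating model without simulating a 30,000-subject
  GWAS.

It does **not** emulate realistic human LD maps, recombination,
X-chromosome inheritance, population substructure, genotyping error or de
novo mutation.  A green simulation test therefore establishes that the
*statistical machinery* is correct under its stated assumptions — not that
the pipeline is robust to real-data artefacts such as strand ambiguity
(ambiguous A/T, C/G variants are matched by exact allele pair only and
surface in the drop log) or imputation structure.

All randomness flows from one master seed through named substreams
(founders, transmission, environment, sumstats, null ensemble, ...), and
every generator restores the caller's RNG state, so reruns with one config
are bit-identical.

## 6. Numerical and reporting choices

* Derivative-free variance searches: Brent (1-D, tol 1e-3 on σ², 1e-9 for
  the REML residual) and Nelder–Mead (reltol 1e-10); PQL inner tolerance
  1e-9 on the linear predictor, warm-started across outer evaluations and
  re-initialised for the final fit so results do not depend on the search
  path.
* Diverging coefficients (|β| > 25) abort as suspected complete
  separation rather than returning a silent non-result.
* Exact Mann–Whitney enumeration is used for tie-free samples up to a
  combined n of 20; with ties (where no closed enumeration exists) the
  tie-corrected normal approximation applies at any n, which reproduces
  the two-sided p = 1 convention for identical samples.
* Pearson χ² carries no continuity correction; descriptive MADs are
  unscaled (no 1.4826), percentages round half-up to 1 decimal — all
  printed-table conventions.
* One descriptive reference value could not be reproduced: the published
  table this convention set mirrors prints 62.1% for counts 103/166,
  whereas 103/166 = 62.048 → 62.0 under half-up rounding and the four
  neighbouring percentages verify exactly; the package reports 62.0 and
  treats the 62.1 as a transcription error.

## 7. Known limitations

* PQL Wald inference is approximate for binary traits in small, deeply
  related samples; the type-I calibration test bounds the practical error
  at the simulated scale but extreme tail p-values inherit PQL's known
  conservatism/anticonservatism trade-offs.
* LDSC here is the single-step weighted fit without block-jackknife
  standard errors or sample-overlap intercept modelling; it supplies point
  estimates to the conditional correction, nothing more.
* The null-calibration fast path fixes variance components at their
  no-score estimates; its agreement with full logistic fits is verified in
  rank terms on small ensembles, not proven in general.
* The simulator's case/control arm uses rejection sampling, which becomes
  slow for very low prevalences with large case quotas; scale `n_variants`
  and quotas together.
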