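# Shared fixtures, built in code and memoised for the session.

fx_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, fx_env)) assign(key, force(expr), fx_env)
  get(key, fx_env)
}

# hand-built effect panel with chosen MAFs and per-allele effects
manual_effect_panel <- function(maf, beta = NULL, disorders = "BD",
                                h2 = NULL) {
  m <- length(maf)
  out <- data.frame(variant_id = sprintf("snp%05d", seq_len(m)),
                    chr = 1L, bp = seq_len(m) * 1000L,
                    a1 = "A", a2 = "G", maf = maf,
                    stringsAsFactors = FALSE)
  u <- matrix(0, m, length(disorders), dimnames = list(NULL, disorders))
  for (k in disorders) {
    b <- if (is.null(beta)) rep(0, m) else beta
    out[[paste0("beta_", k)]] <- b
    out[[paste0("causal_", k)]] <- b != 0
    u[, k] <- b * sqrt(2 * maf * (1 - maf))
  }
  attr(out, "u") <- u
  attr(out, "disorders") <- disorders
  class(out) <- c("effect_panel", "data.frame")
  out
}

# small summary-statistics table (valid, harmonisable)
manual_stats <- function(beta, p = NULL, se = NULL, info = NULL,
                         a1 = "A", a2 = "G", frq = 0.3, n = 10000) {
  m <- length(beta)
  se <- se %||% rep(0.05, m)
  out <- data.frame(SNP = sprintf("snp%05d", seq_len(m)), CHR = 1L,
                    BP = seq_len(m) * 1000L,
                    A1 = rep_len(a1, m), A2 = rep_len(a2, m),
                    BETA = beta, SE = se,
                    P = p %||% (2 * pnorm(-abs(beta / se))),
                    INFO = info %||% rep(1, m),
                    FRQ = rep_len(frq, m), N = n,
                    stringsAsFactors = FALSE)
  class(out) <- c("summary_stats", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small end-to-end study reused across test files
small_study <- function() {
  memo("small_study", {
    cfg <- sim_config(n_variants = 300L, n_families = 4L,
                      n_cc_cases = 12L, n_cc_controls = 25L,
                      gwas_n = c(BD = 20000, SCZ = 20000, MDD = 40000,
                                 NEG = 20000),
                      seed = 42L)
    simulate_cohort(cfg)
  })
}

# sibling-pair pedigree: n_fam trios of founder couple + 2 children
sib_pair_panel <- function(n_fam, effect_panel, seed) {
  ped <- do.call(rbind, lapply(seq_len(n_fam), function(f) {
    fid <- sprintf("SF%03d", f)
    data.frame(fid = fid,
               iid = paste0(fid, c("_P1", "_P2", "_K1", "_K2")),
               pat = c("0", "0", paste0(fid, "_P1"), paste0(fid, "_P1")),
               mat = c("0", "0", paste0(fid, "_P2"), paste0(fid, "_P2")),
               sex = c(1L, 2L, 1L, 2L), generation = c(1L, 1L, 2L, 2L),
               married_in = FALSE, stringsAsFactors = FALSE)
  }))
  founders <- simulate_founders(2L * n_fam, effect_panel, seed = seed,
                                ids = ped$iid[ped$pat == "0"])
  list(pedigree = ped, panel = gene_drop(ped, founders, seed = seed + 1L))
}
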