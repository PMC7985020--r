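#' Gene-drop genotypes through a pedigree
#'
#' Transmits founder haplotypes down a pedigree: each child receives, per
#' variant independently, one uniformly chosen haplotype from each parent.
#'
#' @param pedigree data.frame with columns `iid`, `pat`, `mat` ("0" for no
#'   parent); founders are rows with both parents "0".
#' @param founder_panel Phased [dosage_panel()] whose row names cover every
#'   founder `iid`.
#' @param seed Integer seed.
#' @return A phased `dosage_panel` over all pedigree members, rows in
#'   pedigree order.
#' @export
gene_drop <- function(pedigree, founder_panel, seed) {
  if (is.null(founder_panel$h1))
    stop_famprs("founder panel must be phased (h1/h2 present)")
  n <- nrow(pedigree)
  m <- ncol(founder_panel$dosage)
  is_founder <- pedigree$pat == "0" & pedigree$mat == "0"
  bad <- !is_founder & (pedigree$pat == "0" | pedigree$mat == "0" |
                          !(pedigree$pat %in% pedigree$iid) |
                          !(pedigree$mat %in% pedigree$iid))
  if (any(bad))
    stop_famprs("missing parent for non-founder subject(s): ",
                paste(pedigree$iid[bad], collapse = ", "))
  miss <- setdiff(pedigree$iid[is_founder], rownames(founder_panel$dosage))
  if (length(miss))
    stop_famprs("founder genotypes missing for: ",
                paste(miss, collapse = ", "))

  h1 <- matrix(NA_integer_, n, m, dimnames = list(pedigree$iid, NULL))
  h2 <- h1
  h1[pedigree$iid[is_founder], ] <-
    founder_panel$h1[pedigree$iid[is_founder], , drop = FALSE]
  h2[pedigree$iid[is_founder], ] <-
    founder_panel$h2[pedigree$iid[is_founder], , drop = FALSE]

  done <- is_founder
  with_substream(seed, "transmission", {
    while (!all(done)) {
      ready <- which(!done &
                       pedigree$pat %in% pedigree$iid[done] &
                       pedigree$mat %in% pedigree$iid[done])
      if (!length(ready))
        stop_famprs("pedigree contains a cycle or unresolvable ordering")
      for (i in ready) {
        p <- pedigree$pat[i]; q <- pedigree$mat[i]
        pick <- runif(m) < 0.5
        h1[i, ] <- ifelse(pick, h1[p, ], h2[p, ])
        pick <- runif(m) < 0.5
        h2[i, ] <- ifelse(pick, h1[q, ], h2[q, ])
        done[i] <- TRUE
      }
    }
  })
  dosage_panel(h1 + h2, founder_panel$variants, h1 = h1, h2 = h2)
}

# Build one family's pedigree skeleton (no genotypes).  Generation 1 is a
# founding couple; children of non-terminal generations marry in a spouse
# with probability marry_prob and reproduce.
build_family_skeleton <- function(config, fid, marry_prob = 0.9) {
  gmax <- config$generations_per_family
  lam <- max(config$children_per_couple - 1, 0)
  ped <- data.frame(fid = fid,
                    iid = paste0(fid, "_I001"),
                    pat = "0", mat = "0", sex = 1L,
                    generation = 1L, married_in = FALSE,
                    stringsAsFactors = FALSE)
  ped <- rbind(ped, within(ped, {
    iid <- paste0(fid, "_I002"); sex <- 2L
  }))
  nid <- 2L
  new_id <- function() {
    nid <<- nid + 1L
    sprintf("%s_I%03d", fid, nid)
  }
  couples <- list(c(ped$iid[1], ped$iid[2]))
  for (g in seq_len(gmax - 1L)) {
    next_couples <- list()
    for (cp in couples) {
      n_kids <- 1L + rpois(1, lam)
      for (k in seq_len(n_kids)) {
        kid <- new_id()
        sex <- sample(1:2, 1)
        ped <- rbind(ped, data.frame(
          fid = fid, iid = kid, pat = cp[1], mat = cp[2], sex = sex,
          generation = g + 1L, married_in = FALSE, stringsAsFactors = FALSE))
        if (g + 1L < gmax && runif(1) < marry_prob) {
          sp <- new_id()
          ped <- rbind(ped, data.frame(
            fid = fid, iid = sp, pat = "0", mat = "0", sex = 3L - sex,
            generation = g + 1L, married_in = TRUE, stringsAsFactors = FALSE))
          next_couples[[length(next_couples) + 1L]] <-
            if (sex == 1L) c(kid, sp) else c(sp, kid)
        }
      }
    }
    couples <- next_couples
  }
  ped
}

# Choose, for each target score, an unused candidate whose score best
# matches r * z_target + sqrt(1-r^2) * noise (rank matching when noise-free
# targets are used over full vectors).  Returns candidate indices.
match_assortative <- function(target_scores, candidate_scores, r) {
  # both sides standardised against the candidate pool (same scale)
  mu <- mean(candidate_scores)
  sdv <- sd(candidate_scores)
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  zc <- (candidate_scores - mu) / sdv
  zt <- (target_scores - mu) / sdv
  used <- rep(FALSE, length(candidate_scores))
  out <- integer(length(target_scores))
  for (i in seq_along(target_scores)) {
    want <- r * zt[i] + sqrt(1 - r^2) * rnorm(1)
    free <- which(!used)
    j <- free[which.min(abs(zc[free] - want))]
    used[j] <- TRUE
    out[i] <- j
  }
  out
}

# Simulate one family: skeleton, founder/married-in genotypes with
# assortative mating on the true BD genetic score, then gene dropping.
simulate_family <- function(config, effect_panel, fid, seed,
                            founder_enrichment = 0) {
  with_substream(seed, paste0("family_", fid),
                 simulate_family_impl(config, effect_panel, fid, seed,
                                      founder_enrichment))
}

simulate_family_impl <- function(config, effect_panel, fid, seed,
                                 founder_enrichment) {
  ped <- build_family_skeleton(config, fid)
  need <- ped$iid[ped$pat == "0"]
  r <- config$assortative_mating_strength
  ncand <- max(4L * length(need), 24L)
  pool <- simulate_founders(ncand, effect_panel,
                            seed = substream_seed(seed, paste0("pool", fid)),
                            ids = sprintf("%s_C%04d", fid, seq_len(ncand)))
  g_bd <- true_genetic_scores(pool, effect_panel, config$h2)[, "BD"]

  used <- rep(FALSE, ncand)
  take <- function(idx) {
    used[idx] <<- TRUE
    idx
  }
  assigned <- integer(0)
  names_assigned <- character(0)
  # founding couple: optionally enriched for genetic BD risk
  free <- which(!used)
  i1 <- if (founder_enrichment > 0) {
    thr <- quantile(g_bd, 1 - founder_enrichment)
    cand <- free[g_bd[free] >= thr]
    if (!length(cand)) free[which.max(g_bd[free])] else sample(cand, 1)
  } else sample(free, 1)
  take(i1)
  # spouse of founder 1 by assortative matching
  free <- which(!used)
  i2 <- free[match_assortative(g_bd[i1], g_bd[free], r)]
  take(i2)
  assigned <- c(assigned, i1, i2)
  names_assigned <- c(names_assigned, ped$iid[1], ped$iid[2])

  # married-in spouses matched to their partner's mid-parent genetic score,
  # resolved generation by generation (partners are pedigree-born, their
  # expected genetic score is the parents' mean)
  exp_score <- setNames(rep(NA_real_, nrow(ped)), ped$iid)
  exp_score[ped$iid[1]] <- g_bd[i1]
  exp_score[ped$iid[2]] <- g_bd[i2]
  for (g in 2:max(ped$generation)) {
    born <- ped$generation == g & ped$pat != "0"
    exp_score[ped$iid[born]] <-
      (exp_score[ped$pat[born]] + exp_score[ped$mat[born]]) / 2
    mi <- which(ped$generation == g & ped$married_in)
    for (i in mi) {
      # partner: the pedigree-born member this spouse forms a couple with
      kids <- ped$iid[ped$pat == ped$iid[i] | ped$mat == ped$iid[i]]
      partner <- if (length(kids)) {
        k1 <- kids[1]
        setdiff(c(ped$pat[ped$iid == k1], ped$mat[ped$iid == k1]),
                ped$iid[i])
      } else character(0)
      free <- which(!used)
      pscore <- if (length(partner)) exp_score[partner] else 0
      j <- free[match_assortative(pscore, g_bd[free], r)]
      take(j)
      assigned <- c(assigned, j)
      names_assigned <- c(names_assigned, ped$iid[i])
      exp_score[ped$iid[i]] <- g_bd[j]
    }
  }
  founders <- subset_panel(pool, subjects = assigned)
  rownames(founders$dosage) <- rownames(founders$h1) <-
    rownames(founders$h2) <- names_assigned
  panel <- gene_drop(ped, founders, seed = substream_seed(seed, fid))
  list(pedigree = ped, panel = panel)
}
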