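# Independent oracle implementations and small fixture builders shared by
# the suite. Everything here is deliberately written scalar-style, directly
# from the published estimator formulas, so it shares no code path with the
# package internals it checks.

# Build a genotype table from a list: pop -> locus -> 2-col matrix of alleles
make_gt <- function(spec) {
  pops <- names(spec)
  loci <- names(spec[[1L]])
  ind <- character(0); popv <- character(0)
  al <- setNames(lapply(loci, function(l) NULL), loci)
  for (p in pops) {
    n <- nrow(spec[[p]][[1L]])
    ind <- c(ind, sprintf("%s_i%02d", p, seq_len(n)))
    popv <- c(popv, rep(p, n))
    for (l in loci) al[[l]] <- rbind(al[[l]], spec[[p]][[l]])
  }
  genotype_table(ind, popv, al)
}

pairs_mat <- function(...) matrix(c(...), ncol = 2L, byrow = TRUE)

# Weir & Cockerham (1984) theta, scalar translation of the published
# per-allele component formulas (multiallelic, possibly unequal n).
wc_theta_oracle <- function(gt, pops = NULL) {
  if (is.null(pops)) pops <- unique(gt$population)
  loci <- attr(gt, "loci")
  A_sum <- ABC_sum <- 0
  for (l in loci) {
    a1 <- gt[[paste0(l, "_1")]]; a2 <- gt[[paste0(l, "_2")]]
    keep <- gt$population %in% pops & a1 > 0
    a1 <- a1[keep]; a2 <- a2[keep]; popv <- gt$population[keep]
    alleles <- sort(unique(c(a1, a2)))
    r <- length(pops)
    n_i <- sapply(pops, function(p) sum(popv == p))
    if (any(n_i == 0)) next
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    for (al in alleles) {
      p_i <- sapply(pops, function(p) {
        sel <- popv == p
        (sum(a1[sel] == al) + sum(a2[sel] == al)) / (2 * sum(sel))
      })
      h_i <- sapply(pops, function(p) {
        sel <- popv == p
        sum(sel & ((a1 == al) != (a2 == al))) / sum(sel)
      })
      pbar <- sum(n_i * p_i) / (r * nbar)
      s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n_i * h_i) / (r * nbar)
      a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                    (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      A_sum <- A_sum + a
      ABC_sum <- ABC_sum + a + b + cc
    }
  }
  A_sum / ABC_sum
}

# Nei & Chesser (1983) corrected Hs/Ht/Gst for one locus, from per-pop
# frequency vectors, sample sizes and observed het fractions.
nc_gst_oracle <- function(freq_list, n_vec, ho_vec) {
  r <- length(freq_list)
  n_harm <- r / sum(1 / n_vec)
  ho <- mean(ho_vec)
  hs <- n_harm / (n_harm - 1) *
    (1 - mean(sapply(freq_list, function(p) sum(p^2))) - ho / (2 * n_harm))
  all_alleles <- sort(unique(unlist(lapply(freq_list, names))))
  pbar <- sapply(all_alleles, function(a)
    mean(sapply(freq_list, function(p) if (a %in% names(p)) p[[a]] else 0)))
  ht <- 1 - sum(pbar^2) + hs / (n_harm * r) - ho / (2 * n_harm * r)
  list(hs = hs, ht = ht, gst = (ht - hs) / ht)
}

# Nei (1972) standard distance from two sets of per-locus frequency vectors.
nei_d_oracle <- function(fx, fy) {
  jx <- mean(sapply(fx, function(p) sum(p^2)))
  jy <- mean(sapply(fy, function(p) sum(p^2)))
  jxy <- mean(mapply(function(px, py) {
    alleles <- union(names(px), names(py))
    sum(sapply(alleles, function(a)
      (if (a %in% names(px)) px[[a]] else 0) * (if (a %in% names(py)) py[[a]] else 0)))
  }, fx, fy))
  -log(jxy / sqrt(jx * jy))
}

# Henderson method-III / ANOVA expected-mean-squares components for a
# BALANCED design: b blocks x p provenances x f families x n per cell.
henderson_varcomp <- function(d) {
  d$fam_id <- interaction(d$provenance, d$family, drop = TRUE)
  b <- length(unique(d$block))
  p <- length(unique(d$provenance))
  f <- length(unique(d$fam_id)) / p
  n <- nrow(d) / (b * p * f)
  stopifnot(n == round(n))
  fit <- aov(value ~ factor(block) + provenance + fam_id, data = d)
  ms <- summary(fit)[[1L]][, "Mean Sq"]
  names(ms) <- trimws(rownames(summary(fit)[[1L]]))
  ms_p <- ms[["provenance"]]; ms_f <- ms[["fam_id"]]; ms_e <- ms[["Residuals"]]
  s2F <- max((ms_f - ms_e) / (b * n), 0)
  s2P <- max((ms_p - ms_f) / (f * b * n), 0)
  list(sigma2_P = s2P, sigma2_F = s2F, sigma2_E = ms_e)
}

# Exhaustive Mantel p over all relabelings (small n only).
mantel_exhaustive_p <- function(mA, mB, tail = "one_sided_positive") {
  n <- nrow(mA)
  perms <- gtools_permutations(n)
  lt <- lower.tri(mA)
  r_obs <- cor(mA[lt], mB[lt])
  rs <- apply(perms, 1L, function(pp) {
    mBp <- mB[pp, pp]
    cor(mA[lt], mBp[lt])
  })
  if (tail == "one_sided_positive") mean(rs >= r_obs - 1e-12)
  else mean(abs(rs) >= abs(r_obs) - 1e-12)
}

gtools_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- gtools_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# Additive distance matrix from a tree's leaf-to-leaf path lengths.
tree_path_matrix <- function(tree) ape::cophenetic.phylo(tree)
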