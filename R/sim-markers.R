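#' Configuration for island-model SSR simulation
#'
#' Defines a Balding-Nichols island model: every population's allele
#' frequency vector at a locus is drawn from a Dirichlet distribution
#' centred on the ancestral frequencies with concentration
#' `(1 - F) / F`, so the expected differentiation equals the `target_fst`
#' dial. Defaults emulate a highly polymorphic SSR panel (8 alleles per
#' locus, expected heterozygosity around 0.8) at the differentiation level
#' typical of a wind-pollinated tree (multilocus F_ST near 0.086).
#'
#' @param n_pops number of populations (>= 1).
#' @param n_loci number of loci (>= 1).
#' @param n_per_pop diploid individuals per population (>= 1).
#' @param target_fst drift parameter F in [0, 1).
#' @param ancestral_allele_freqs optional list of per-locus probability
#'   vectors (each summing to 1 within 1e-12). When `NULL`, one vector per
#'   locus is drawn from a symmetric Dirichlet(2) over `n_alleles` alleles
#'   using `seed`.
#' @param n_alleles alleles per locus when ancestral frequencies are drawn.
#' @param seed integer seed; all random streams derive from it.
#' @return object of class `marker_sim_config`.
#' @export
marker_sim_config <- function(n_pops = 31L, n_loci = 15L, n_per_pop = 15L,
                              target_fst = 0.086,
                              ancestral_allele_freqs = NULL,
                              n_alleles = 8L, seed = 1L) {
  stopifnot(n_pops >= 1L, n_loci >= 1L, n_per_pop >= 1L, n_alleles >= 1L)
  if (!is.numeric(target_fst) || target_fst < 0 || target_fst >= 1)
    stop("target_fst must lie in [0, 1)")
  if (is.null(ancestral_allele_freqs)) {
    ancestral_allele_freqs <- with_seed(derive_seed(seed, "ancestral"), {
      lapply(seq_len(n_loci), function(i) {
        g <- stats::rgamma(n_alleles, shape = 2)
        g / sum(g)
      })
    })
  }
  if (length(ancestral_allele_freqs) != n_loci)
    stop("ancestral_allele_freqs must have one vector per locus")
  for (p in ancestral_allele_freqs) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-12)
      stop("ancestral allele frequencies must be a probability simplex (sum 1 within 1e-12)")
  }
  names(ancestral_allele_freqs) <- sprintf("L%02d", seq_len(n_loci))
  structure(list(n_pops = as.integer(n_pops), n_loci = as.integer(n_loci),
                 n_per_pop = as.integer(n_per_pop), target_fst = target_fst,
                 ancestral_allele_freqs = ancestral_allele_freqs,
                 seed = as.integer(seed)),
            class = "marker_sim_config")
}

#' Draw per-population allele frequencies under the island model
#'
#' For drift parameter F > 0, each population x locus vector is Dirichlet
#' with parameters `p_ancestral * (1 - F) / F` (Balding-Nichols). F = 0
#' returns the ancestral frequencies unchanged for every population.
#' Degenerate loci (an ancestral frequency of 1) stay monomorphic.
#'
#' @param cfg a `marker_sim_config`.
#' @return list of class `sim_freqs`: `freq[[locus]]` is a populations x
#'   alleles matrix; plus `pops`, `loci`, `ancestral`, `target_fst`.
#' @export
simulate_allele_freqs <- function(cfg) {
  stopifnot(inherits(cfg, "marker_sim_config"))
  pops <- sprintf("pop%02d", seq_len(cfg$n_pops))
  loci <- names(cfg$ancestral_allele_freqs)
  F <- cfg$target_fst
  freq <- with_seed(derive_seed(cfg$seed, "freqs"), {
    lapply(loci, function(l) {
      p <- cfg$ancestral_allele_freqs[[l]]
      k <- length(p)
      m <- if (F == 0) {
        matrix(rep(p, each = cfg$n_pops), nrow = cfg$n_pops)
      } else {
        alpha <- p * (1 - F) / F
        t(vapply(seq_len(cfg$n_pops), function(i) {
          g <- vapply(alpha, function(a) if (a == 0) 0 else stats::rgamma(1L, shape = a),
                      numeric(1L))
          if (sum(g) == 0) { out <- numeric(k); out[which.max(p)] <- 1; out }
          else g / sum(g)
        }, numeric(k)))
      }
      dimnames(m) <- list(pops, as.character(seq_len(k)))
      m
    })
  })
  names(freq) <- loci
  structure(list(pops = pops, loci = loci, freq = freq,
                 ancestral = cfg$ancestral_allele_freqs,
                 target_fst = F),
            class = "sim_freqs")
}

#' Draw diploid genotypes from population allele frequencies
#'
#' Each individual's genotype at a locus is two independent allele draws
#' from its population's frequency vector (Hardy-Weinberg proportions
#' within populations). Deterministic given `seed`.
#'
#' @param freqs a `sim_freqs` object from [simulate_allele_freqs()].
#' @param n_per_pop diploids per population (scalar or per-population
#'   vector, >= 1).
#' @param seed integer seed.
#' @return a [genotype_table()].
#' @export
simulate_genotypes <- function(freqs, n_per_pop, seed = 1L) {
  stopifnot(inherits(freqs, "sim_freqs"))
  n_per_pop <- rep_len(as.integer(n_per_pop), length(freqs$pops))
  if (any(n_per_pop < 1L)) stop("n_per_pop must be >= 1")
  pop_col <- rep(freqs$pops, n_per_pop)
  ind <- sprintf("%s_%03d", pop_col, unlist(lapply(n_per_pop, seq_len)))
  al <- with_seed(derive_seed(seed, "genotypes"), {
    lapply(freqs$loci, function(l) {
      P <- freqs$freq[[l]]
      k <- ncol(P)
      draws <- lapply(seq_along(freqs$pops), function(i) {
        matrix(sample.int(k, 2L * n_per_pop[i], replace = TRUE, prob = P[i, ]),
               ncol = 2L)
      })
      do.call(rbind, draws)
    })
  })
  names(al) <- freqs$loci
  genotype_table(ind, pop_col, al)
}

#' One-call island-model genotype simulation
#'
#' Convenience wrapper: builds the config, draws frequencies, draws
#' genotypes, and returns the ground truth alongside the data.
#'
#' @inheritParams marker_sim_config
#' @return list: `genotypes` (a `genotype_table`), `truth` (list with the
#'   realized per-population frequencies, ancestral frequencies and the
#'   F_ST dial).
#' @export
simulate_markers <- function(n_pops = 31L, n_loci = 15L, n_per_pop = 15L,
                             target_fst = 0.086, seed = 1L, n_alleles = 8L,
                             ancestral_allele_freqs = NULL) {
  cfg <- marker_sim_config(n_pops, n_loci, n_per_pop, target_fst,
                           ancestral_allele_freqs, n_alleles, seed)
  fr <- simulate_allele_freqs(cfg)
  gt <- simulate_genotypes(fr, cfg$n_per_pop, seed = derive_seed(seed, "gt"))
  list(genotypes = gt,
       truth = list(freqs = fr, target_fst = target_fst, config = cfg))
}
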