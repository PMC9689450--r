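#' Hardy-Weinberg equilibrium tests with Bonferroni control
#'
#' Runs one test per population x locus cell. The default is a Monte-Carlo
#' exact test: conditioning on the observed allele counts, alleles are
#' shuffled into random diploid pairings and the conditional probability of
#' each shuffled genotype table is compared with that of the observed table;
#' the p-value is the (add-one corrected) fraction of shuffles whose table is
#' no more probable than the observed one. This handles the many-allele
#' genotype tables typical of SSR loci, where asymptotic chi-square counts
#' are sparse. A chi-square test against expected genotype proportions is
#' available as a fast alternative.
#'
#' Monomorphic cells are skipped and reported as non-applicable. The
#' Bonferroni threshold is `alpha / (n_populations * n_loci)` — all test
#' cells, applicable or not, count toward the correction.
#'
#' @param gt a `genotype_table`.
#' @param method `"exact_mc"` or `"chi2"`.
#' @param n_mc number of Monte-Carlo shuffles (>= 1000 for `exact_mc`).
#' @param alpha family-wise error rate for the Bonferroni verdicts.
#' @param seed integer seed for the Monte-Carlo shuffles.
#' @return data frame with one row per population x locus: `population`,
#'   `locus`, `n`, `p`, `applicable`, `significant`. The Bonferroni
#'   threshold, the number of test cells, and the number of departures are
#'   attached as attributes `threshold`, `n_tests`, `n_departures`.
#' @export
hwe_tests <- function(gt, method = c("exact_mc", "chi2"), n_mc = 10000L,
                      alpha = 0.05, seed = NULL) {
  method <- match.arg(method)
  if (method == "exact_mc" && n_mc < 1000L)
    stop("exact_mc requires n_mc >= 1000")
  pops <- gt_populations(gt)
  loci <- gt_loci(gt)
  n_tests <- length(pops) * length(loci)
  threshold <- alpha / n_tests
  rows <- vector("list", n_tests)
  k <- 0L
  with_seed(if (is.null(seed)) NULL else derive_seed(seed, "hwe"), {
    for (pop in pops) {
      sub <- gt[gt$population == pop, , drop = FALSE]
      for (l in loci) {
        k <- k + 1L
        a <- cbind(sub[[paste0(l, "_1")]], sub[[paste0(l, "_2")]])
        a <- a[a[, 1L] > 0L, , drop = FALSE]
        n_typed <- nrow(a)
        n_alleles <- length(unique(c(a)))
        if (n_typed == 0L || n_alleles < 2L) {
          rows[[k]] <- data.frame(population = pop, locus = l, n = n_typed,
                                  p = NA_real_, applicable = FALSE,
                                  significant = NA)
          next
        }
        p <- if (method == "exact_mc") hwe_exact_mc(a, n_mc) else hwe_chi2(a)
        rows[[k]] <- data.frame(population = pop, locus = l, n = n_typed,
                                p = p, applicable = TRUE,
                                significant = p < threshold)
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, threshold = threshold, n_tests = n_tests,
            n_departures = sum(out$significant, na.rm = TRUE))
}

## Conditional log-probability of a diploid genotype table given its allele
## counts: log[ n! 2^H prod_a(na_a!) / (prod_g n_g!) / (2n)! ].  Terms fixed
## under allele shuffling (allele-count factorials, (2n)!) are retained so
## the value is the exact conditional probability, usable for enumeration.
hwe_table_logprob <- function(g1, g2) {
  n <- length(g1)
  gmin <- pmin(g1, g2); gmax <- pmax(g1, g2)
  key <- paste(gmin, gmax)
  ng <- table(key)
  h <- sum(gmin != gmax)
  na_cnt <- table(c(g1, g2))
  lgamma(n + 1) + h * log(2) + sum(lgamma(na_cnt + 1)) -
    sum(lgamma(ng + 1)) - lgamma(2 * n + 1)
}

hwe_exact_mc <- function(a, n_mc) {
  obs <- hwe_table_logprob(a[, 1L], a[, 2L])
  pool <- c(a[, 1L], a[, 2L])
  n <- nrow(a)
  hits <- 0L
  for (i in seq_len(n_mc)) {
    v <- sample(pool)
    lp <- hwe_table_logprob(v[seq_len(n)], v[n + seq_len(n)])
    if (lp <= obs + 1e-9) hits <- hits + 1L
  }
  (1 + hits) / (n_mc + 1)
}

hwe_chi2 <- function(a) {
  n <- nrow(a)
  alleles <- sort(unique(c(a)))
  p <- as.numeric(table(factor(c(a), levels = alleles))) / (2 * n)
  k <- length(alleles)
  ## observed genotype counts and HWE expectations over all k(k+1)/2 genotypes
  gmin <- pmin(a[, 1L], a[, 2L]); gmax <- pmax(a[, 1L], a[, 2L])
  obs <- exp_cnt <- numeric(0)
  for (i in seq_len(k)) for (j in i:k) {
    obs <- c(obs, sum(gmin == alleles[i] & gmax == alleles[j]))
    exp_cnt <- c(exp_cnt, if (i == j) n * p[i]^2 else 2 * n * p[i] * p[j])
  }
  stat <- sum((obs - exp_cnt)^2 / pmax(exp_cnt, .Machine$double.eps))
  df <- k * (k - 1) / 2
  stats::pchisq(stat, df = df, lower.tail = FALSE)
}

#' Exact HWE p-value by full enumeration (biallelic)
#'
#' Enumerates every heterozygote count compatible with the observed allele
#' counts at a biallelic locus and sums the conditional probabilities of all
#' tables no more probable than the observed one. Used as the reference
#' against which the Monte-Carlo exact test is validated; practical only for
#' two alleles.
#'
#' @param n_aa,n_ab,n_bb observed genotype counts.
#' @return exact p-value.
#' @export
hwe_exact_enumerate <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  hets <- seq(n_ab %% 2, min(n_a, 2 * n - n_a), by = 2)
  logp <- vapply(hets, function(h) {
    aa <- (n_a - h) / 2; bb <- n - aa - h
    if (aa < 0 || bb < 0) return(-Inf)
    lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1) +
      h * log(2) + lgamma(n_a + 1) + lgamma(2 * n - n_a + 1) - lgamma(2 * n + 1)
  }, numeric(1L))
  pr <- exp(logp)
  obs <- pr[hets == n_ab]
  sum(pr[pr <= obs + 1e-12])
}
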