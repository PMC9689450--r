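#' Nei-Chesser G_ST per locus and multilocus
#'
#' Sample-size-corrected gene-diversity partition (Nei & Chesser 1983).
#' With r populations, harmonic-mean sample size n_tilde, observed
#' heterozygosity Ho (mean over populations) and per-population frequency
#' vectors p_i:
#' \deqn{Hs = n/(n-1) (1 - mean_i sum_a p_{ia}^2 - Ho/(2n))}
#' \deqn{Ht = 1 - sum_a pbar_a^2 + Hs/(n r) - Ho/(2 n r)}
#' where pbar is the unweighted mean frequency across populations, and
#' G_ST = (Ht - Hs)/Ht. The multilocus value is the ratio of Hs and Ht
#' averaged across loci. Negative per-locus estimates are reported as
#' computed. Globally monomorphic loci (Ht = 0) are undefined and excluded
#' from the multilocus average with a warning.
#'
#' @param gt a `genotype_table` or `allele_freqs`.
#' @return list of class `locus_differentiation`: `per_locus` data frame
#'   (`locus`, `hs`, `ht`, `gst`), `multilocus` (scalar G_ST),
#'   `hs_mean`, `ht_mean`.
#' @export
gst <- function(gt) {
  af <- if (inherits(gt, "allele_freqs")) gt else allele_frequencies(gt)
  rows <- lapply(af$loci, function(l) {
    use <- af$n[, l] > 0L
    if (sum(use) < 2L)
      return(data.frame(locus = l, hs = NA_real_, ht = NA_real_, gst = NA_real_))
    n_i <- af$n[use, l]
    fr <- af$freq[[l]][use, , drop = FALSE]
    ho <- mean(af$ho[use, l])
    r <- sum(use)
    n_harm <- r / sum(1 / n_i)
    hs <- n_harm / (n_harm - 1) * (1 - mean(rowSums(fr^2)) - ho / (2 * n_harm))
    pbar <- colMeans(fr)
    ht <- 1 - sum(pbar^2) + hs / (n_harm * r) - ho / (2 * n_harm * r)
    data.frame(locus = l, hs = hs, ht = ht,
               gst = if (abs(ht) < 1e-12) NA_real_ else (ht - hs) / ht)
  })
  per_locus <- do.call(rbind, rows)
  undef <- is.na(per_locus$gst)
  if (any(undef))
    warning("G_ST undefined at ", sum(undef),
            " locus/loci (globally monomorphic or <2 populations); excluded from multilocus value")
  hs_mean <- mean(per_locus$hs[!undef])
  ht_mean <- mean(per_locus$ht[!undef])
  structure(list(per_locus = per_locus, multilocus = (ht_mean - hs_mean) / ht_mean,
                 hs_mean = hs_mean, ht_mean = ht_mean),
            class = "locus_differentiation")
}

#' @export
print.locus_differentiation <- function(x, ...) {
  print(x$per_locus)
  cat("Multilocus G_ST:", format(x$multilocus, digits = 4), "\n")
  invisible(x)
}

## Weir & Cockerham (1984) variance components per locus, multiallelic.
## Returns c(a, abc) summed over alleles for the given populations.
wc_locus_components <- function(cnt, hetm, n_i) {
  use <- n_i > 0L
  cnt <- cnt[use, , drop = FALSE]
  hetm <- hetm[use, , drop = FALSE]
  n_i <- n_i[use]
  r <- length(n_i)
  if (r < 2L) return(c(a = NA_real_, abc = NA_real_))
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  p_i <- cnt / (2 * n_i)                 # pops x alleles
  h_i <- hetm / n_i                      # fraction of individuals het for allele a
  pbar <- colSums(n_i * p_i) / (r * nbar)
  s2 <- colSums(n_i * (p_i - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  hbar <- colSums(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = sum(a), abc = sum(a + b + cc))
}

## Per-locus (a, abc) components for a set of populations; rows = loci.
wc_components <- function(af, pops = af$pops) {
  idx <- match(pops, af$pops)
  t(vapply(af$loci, function(l) {
    wc_locus_components(af$counts[[l]][idx, , drop = FALSE],
                        af$het[[l]][idx, , drop = FALSE],
                        af$n[idx, l])
  }, c(a = 0, abc = 0)))
}

#' Multilocus Weir-Cockerham theta
#'
#' Weir & Cockerham's (1984) F_ST estimator, combined over loci as the ratio
#' of summed among-population components to summed total components.
#'
#' @param gt a `genotype_table` or `allele_freqs`.
#' @return scalar theta (may be negative); per-locus components attached as
#'   attribute `components` (loci x (a, abc) matrix).
#' @export
wc_theta <- function(gt) {
  af <- if (inherits(gt, "allele_freqs")) gt else allele_frequencies(gt)
  comp <- wc_components(af)
  ok <- !is.na(comp[, "abc"]) & comp[, "abc"] != 0
  structure(sum(comp[ok, "a"]) / sum(comp[ok, "abc"]), components = comp)
}

#' Pairwise multilocus Weir-Cockerham theta matrix
#'
#' For every unordered pair of populations, computes multilocus theta over
#' the loci with data in both members. Estimates are reported untruncated
#' (negative values possible); use `truncate = TRUE` when the matrix feeds a
#' distance-based method.
#'
#' @param gt a `genotype_table` or `allele_freqs`.
#' @param truncate clamp negative estimates to 0.
#' @return symmetric matrix with zero diagonal, of class `matrix`.
#' @export
pairwise_fst <- function(gt, truncate = FALSE) {
  af <- if (inherits(gt, "allele_freqs")) gt else allele_frequencies(gt)
  pops <- af$pops
  if (length(pops) < 2L) stop("need >= 2 populations")
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)[-1L]) for (j in seq_len(i - 1L)) {
    pair <- pops[c(i, j)]
    cotyped <- af$n[pair[1L], ] > 0L & af$n[pair[2L], ] > 0L
    if (!any(cotyped))
      stop("populations ", pair[1L], " and ", pair[2L], " share no co-typed loci")
    comp <- wc_components(af, pair)[cotyped, , drop = FALSE]
    ok <- !is.na(comp[, "abc"]) & comp[, "abc"] != 0
    th <- sum(comp[ok, "a"]) / sum(comp[ok, "abc"])
    if (truncate) th <- max(th, 0)
    m[i, j] <- m[j, i] <- th
  }
  m
}

#' Nei (1972) standard genetic distance matrix
#'
#' D = -ln( Jxy / sqrt(Jx * Jy) ), where Jx, Jy, Jxy are homozygosity and
#' shared-identity sums averaged over loci. Pairs with zero shared identity
#' get `Inf` with a warning.
#'
#' @param gt a `genotype_table` or `allele_freqs`.
#' @param loci optional subset/resample of loci (indices or names; repeats
#'   allowed, supporting locus bootstraps).
#' @return symmetric matrix with zero diagonal.
#' @export
nei_distance <- function(gt, loci = NULL) {
  af <- if (inherits(gt, "allele_freqs")) gt else allele_frequencies(gt)
  jt <- nei_identity_tables(af)
  nei_distance_from_identity(jt, loci)
}

## Per-locus identity tables: jx[pop, locus] = sum p^2, jxy[[locus]] = P P^T.
nei_identity_tables <- function(af) {
  jx <- vapply(af$loci, function(l) rowSums(af$freq[[l]]^2), numeric(length(af$pops)))
  jx <- matrix(jx, nrow = length(af$pops),
               dimnames = list(af$pops, af$loci))
  jxy <- lapply(af$loci, function(l) {
    P <- af$freq[[l]]
    P %*% t(P)
  })
  names(jxy) <- af$loci
  list(pops = af$pops, loci = af$loci, jx = jx, jxy = jxy)
}

nei_distance_from_identity <- function(jt, loci = NULL) {
  loci <- if (is.null(loci)) jt$loci else {
    if (is.numeric(loci)) jt$loci[loci] else loci
  }
  jx <- rowMeans(jt$jx[, loci, drop = FALSE])
  jxy <- Reduce(`+`, jt$jxy[loci]) / length(loci)
  I <- jxy / sqrt(outer(jx, jx))
  D <- -log(I)
  diag(D) <- 0
  if (any(is.infinite(D)))
    warning("zero shared allele identity for ", sum(is.infinite(D)) / 2,
            " pair(s); distance reported as Inf")
  dimnames(D) <- list(jt$pops, jt$pops)
  (D + t(D)) / 2
}
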