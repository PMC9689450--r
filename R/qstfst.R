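#' Q_ST-F_ST neutrality test for one trait
#'
#' Tests whether a trait's quantitative differentiation departs from the
#' neutral expectation set by the markers. The observed statistic is
#' Q_ST - F_ST, with Q_ST from the half-sib REML fit and F_ST the
#' multilocus Weir-Cockerham theta. The null distribution of the
#' difference is built by resampling (half-sib dam-design scheme):
#' \enumerate{
#'   \item bootstrap theta* over loci (sampling loci with replacement and
#'     recombining their variance components);
#'   \item draw the neutral provenance and family variance components from
#'     their sampling distributions: the design mean squares are drawn as
#'     scaled chi-squares — MS_E* on the residual df, MS_F* on df_F =
#'     n_families - n_pops, MS_P* on df_P = n_pops - 1, with expectations
#'     set by the fitted sigma2_E, sigma2_F and the neutral
#'     sigma2_P_neutral = 8 * sigma2_F_hat * theta* / (1 - theta*) (so
#'     that E(Q_ST) = theta* under neutrality) — and the components are
#'     recovered by the moment equations sigma2_F* = (MS_F* - MS_E*)/k_F,
#'     sigma2_P* = (MS_P* - MS_F*)/k_P, with balanced-design coefficients
#'     k_F = observations per family and k_P = observations per
#'     provenance (averages when the design is unbalanced). Components
#'     are deliberately not truncated at zero, matching the sampling
#'     noise of moment estimators;
#'   \item form Q_ST* - theta*.
#' }
#' The two-tailed p-value is 2 x the smaller tail fraction with add-one
#' correction, capped at 1; 2.5% and 97.5% null quantiles are reported as
#' critical values, and the direction call is `divergent` when the observed
#' difference exceeds the upper critical value, `uniform` below the lower,
#' `neutral` otherwise.
#'
#' @param tt trait table (long format; see [fit_varcomp()]).
#' @param gt a `genotype_table` (>= 5 loci, >= 3 populations).
#' @param trait,year trait and year to test.
#' @param n_resamples null draws (default 10,000).
#' @param seed integer seed.
#' @return object of class `qstfst_result`: list with `trait`, `year`,
#'   `qst`, `fst`, `observed_diff`, `crit_lo`, `crit_hi`, `p_two_tailed`,
#'   `direction`, `n_resamples`, `seed`, `converged`, `null_mean`, and the
#'   full `null` vector.
#' @export
qst_fst_test <- function(tt, gt, trait = NULL, year = NULL,
                         n_resamples = 10000L, seed = 1L,
                         truncate_null = TRUE) {
  if (length(gt_loci(gt)) < 5L)
    stop("refusing to build the null from < 5 loci (locus bootstrap too coarse)")
  if (length(gt_populations(gt)) < 3L)
    stop("refusing to build the null from < 3 populations")
  theta <- wc_theta(gt)
  comp <- attr(theta, "components")
  comp <- comp[!is.na(comp[, "abc"]) & comp[, "abc"] != 0, , drop = FALSE]
  vc <- fit_varcomp(tt, trait = trait, year = year)
  qst_obs <- qst_from_varcomp(vc)
  obs_diff <- qst_obs - as.numeric(theta)
  if (vc$sigma2_F <= 0)
    stop("family variance estimate is 0: neutral Q_ST* undefined for this trait")
  df_P <- vc$n_prov - 1L
  df_F <- vc$n_fam - vc$n_prov
  if (df_F < 1L) stop("n_families must exceed n_populations for the family df")
  ## design coefficients of the moment equations (exact when balanced,
  ## mean group sizes otherwise)
  d <- select_trait(tt, trait, year)
  k_F <- vc$n_obs / vc$n_fam                   # obs per family
  k_P <- vc$n_obs / vc$n_prov                  # obs per provenance
  n_blocks <- length(unique(d$block))
  df_E <- max(vc$n_obs - vc$n_fam - (n_blocks - 1L), 1L)
  n_loci <- nrow(comp)
  null <- with_seed(derive_seed(seed, "qstfst"), {
    idx <- matrix(sample.int(n_loci, n_resamples * n_loci, replace = TRUE),
                  nrow = n_resamples)
    a_s <- matrix(comp[idx, "a"], nrow = n_resamples)
    abc_s <- matrix(comp[idx, "abc"], nrow = n_resamples)
    theta_star <- rowSums(a_s) / rowSums(abc_s)
    theta_star <- pmin(pmax(theta_star, 1e-6), 1 - 1e-6)
    s2P_neut <- 8 * vc$sigma2_F * theta_star / (1 - theta_star)
    ms_E <- vc$sigma2_E * stats::rchisq(n_resamples, df_E) / df_E
    ms_F <- (vc$sigma2_E + k_F * vc$sigma2_F) *
      stats::rchisq(n_resamples, df_F) / df_F
    ms_P <- (vc$sigma2_E + k_F * vc$sigma2_F + k_P * s2P_neut) *
      stats::rchisq(n_resamples, df_P) / df_P
    s2F_star <- (ms_F - ms_E) / k_F
    s2P_star <- (ms_P - ms_F) / k_P
    if (truncate_null) {
      ## project onto the parameter space, mirroring the REML boundary
      ## constraint applied to the observed components
      s2F_star <- pmax(s2F_star, 0)
      s2P_star <- pmax(s2P_star, 0)
    }
    den <- s2P_star + 8 * s2F_star
    qst_star <- ifelse(den > 0, s2P_star / den, 0)
    qst_star - theta_star
  })
  crit <- stats::quantile(null, c(0.025, 0.975), names = FALSE)
  p_hi <- (1 + sum(null >= obs_diff)) / (n_resamples + 1)
  p_lo <- (1 + sum(null <= obs_diff)) / (n_resamples + 1)
  p <- min(1, 2 * min(p_hi, p_lo))
  direction <- if (obs_diff > crit[2L]) "divergent"
               else if (obs_diff < crit[1L]) "uniform" else "neutral"
  structure(list(trait = vc$trait, year = vc$year,
                 qst = qst_obs, fst = as.numeric(theta),
                 observed_diff = obs_diff,
                 crit_lo = crit[1L], crit_hi = crit[2L],
                 p_two_tailed = p, direction = direction,
                 n_resamples = as.integer(n_resamples), seed = seed,
                 converged = vc$converged,
                 null_mean = mean(null), null = null),
            class = "qstfst_result")
}

#' @export
print.qstfst_result <- function(x, ...) {
  cat(sprintf("Q_ST-F_ST test (%s, year %s):\n", x$trait, x$year))
  cat(sprintf("  Q_ST = %.4f  F_ST = %.4f  diff = %.4f\n", x$qst, x$fst,
              x$observed_diff))
  cat(sprintf("  2.5%% / 97.5%% crit: %.4f / %.4f   p = %.4g   call: %s\n",
              x$crit_lo, x$crit_hi, x$p_two_tailed, x$direction))
  invisible(x)
}

#' Neutrality-test report table
#'
#' One row per trait x year with the observed difference, the 2.5% and
#' 97.5% critical values, the two-tailed p, and significance marks on the
#' two-star convention (`ns` p >= 0.05, `*` 0.01 <= p < 0.05, `**`
#' 0.001 <= p < 0.01, `***` p < 0.001).
#'
#' @param results list of `qstfst_result` objects (or a single one).
#' @return data frame with columns `trait_code`, `qst_fst_diff`,
#'   `crit_lo_2.5`, `crit_hi_97.5`, `p_two_tailed`, `signif`, `direction`.
#' @export
qstfst_table <- function(results) {
  if (inherits(results, "qstfst_result")) results <- list(results)
  stopifnot(length(results) >= 1L)
  out <- do.call(rbind, lapply(results, function(x) {
    data.frame(trait_code = paste0(x$trait, x$year),
               qst_fst_diff = x$observed_diff,
               crit_lo_2.5 = x$crit_lo, crit_hi_97.5 = x$crit_hi,
               p_two_tailed = x$p_two_tailed,
               signif = p_stars(x$p_two_tailed),
               direction = x$direction, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
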