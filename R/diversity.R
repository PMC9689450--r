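#' Per-population SSR diversity statistics
#'
#' For every population x locus cell with data, computes:
#' \itemize{
#'   \item `na` — observed number of alleles;
#'   \item `ne` — effective number of alleles, 1 / sum(p^2);
#'   \item `ho` — observed heterozygote fraction;
#'   \item `h` — Nei gene diversity, 1 - sum(p^2);
#'   \item `he` — unbiased expected heterozygosity, (2n / (2n - 1)) * h;
#'   \item `i` — Shannon information index, -sum(p * log(p));
#'   \item `pic` — polymorphic information content (Botstein et al. 1980),
#'     1 - sum(p^2) - sum over i<j of 2 p_i^2 p_j^2;
#'   \item `fis` — inbreeding coefficient, 1 - ho / h (NA for monomorphic
#'     cells where h = 0).
#' }
#' Population-level values are unweighted means over loci with standard
#' deviations; cells with no typed individuals are excluded from the means.
#'
#' @param gt a `genotype_table`, or an `allele_freqs` object (then `ho`
#'   comes with it).
#' @return an object of class `diversity_summary`: list with `per_locus`
#'   (one row per population x locus) and `by_population` (means +- SD over
#'   loci) data frames.
#' @export
diversity_stats <- function(gt) {
  af <- if (inherits(gt, "allele_freqs")) gt else allele_frequencies(gt)
  rows <- list()
  for (l in af$loci) {
    fr <- af$freq[[l]]
    for (pop in af$pops) {
      n <- af$n[pop, l]
      if (n == 0L) next
      p <- fr[pop, ]
      p <- p[p > 0]
      sum_p2 <- sum(p^2)
      h <- 1 - sum_p2
      he <- (2 * n) / (2 * n - 1) * h
      pic <- locus_pic(p)
      rows[[length(rows) + 1L]] <- data.frame(
        population = pop, locus = l, n = n,
        na = length(p), ne = 1 / sum_p2,
        ho = af$ho[pop, l], he = he, h = h,
        i = -sum(p * log(p)), pic = pic,
        fis = if (h > 0) 1 - af$ho[pop, l] / h else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  per_locus <- do.call(rbind, rows)
  stats_cols <- c("na", "ne", "ho", "he", "h", "i", "pic", "fis")
  by_pop <- do.call(rbind, lapply(split(per_locus, per_locus$population), function(d) {
    out <- data.frame(population = d$population[1L], n_loci = nrow(d))
    for (s in stats_cols) {
      v <- d[[s]][!is.na(d[[s]])]
      out[[s]] <- mean(v)
      out[[paste0(s, "_sd")]] <- sd0(v)
    }
    out
  }))
  by_pop <- by_pop[match(af$pops[af$pops %in% by_pop$population], by_pop$population), ]
  rownames(by_pop) <- NULL
  structure(list(per_locus = per_locus, by_population = by_pop),
            class = "diversity_summary")
}

## Botstein et al. (1980) codominant PIC for one frequency vector.
locus_pic <- function(p) {
  sum_p2 <- sum(p^2)
  cross <- (sum_p2^2 - sum(p^4)) / 2   # sum_{i<j} p_i^2 p_j^2
  1 - sum_p2 - 2 * cross
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat("Diversity summary for", nrow(x$by_population), "populations\n")
  print(utils::head(x$by_population, 10L))
  invisible(x)
}

#' Aggregate per-population diversity statistics
#'
#' Unweighted arithmetic mean and standard deviation of each numeric
#' statistic across populations — the "Mean" row of a per-population
#' diversity table. Accepts either a `diversity_summary` or any data frame
#' with a `population` column and numeric statistic columns (such as a
#' published per-population summary table).
#'
#' @param x a `diversity_summary` or data frame.
#' @param stats columns to aggregate; default: all numeric columns except
#'   `n_loci` and columns ending in `_sd`.
#' @return data frame with columns `stat`, `mean`, `sd`, `n_pops`.
#' @export
aggregate_diversity <- function(x, stats = NULL) {
  df <- if (inherits(x, "diversity_summary")) x$by_population else x
  if (!is.data.frame(df) || nrow(df) == 0L) stop("empty diversity table")
  if (is.null(stats)) {
    num <- vapply(df, is.numeric, logical(1L))
    stats <- setdiff(names(df)[num], "n_loci")
    stats <- stats[!grepl("_sd$", stats)]
  }
  out <- do.call(rbind, lapply(stats, function(s) {
    v <- df[[s]][!is.na(df[[s]])]
    data.frame(stat = s, mean = mean(v), sd = sd0(v), n_pops = length(v),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
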