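#' Fit the half-sib provenance-trial mixed model by REML
#'
#' Model: value = grand mean + fixed block + random provenance +
#' random family-within-provenance + residual. Fitted by REML with
#' variance components constrained non-negative (boundary estimates are
#' reported as 0). Family labels are nested inside provenance, so the
#' random term uses the provenance:family interaction and family codes may
#' repeat across provenances.
#'
#' @param tt trait table: data frame with columns `provenance`, `family`,
#'   `block`, `year`, `trait`, `value` (and optionally `individual`).
#' @param trait trait code to fit (default: the only trait present).
#' @param year year to fit (default: the only year present).
#' @return object of class `variance_components`: list with `sigma2_P`,
#'   `sigma2_F`, `sigma2_E`, `blocks` (fixed-effect estimates, first block
#'   absorbed in the intercept), `grand_mean`, `loglik`, `converged`,
#'   `n_obs`, `n_prov`, `n_fam`.
#' @export
fit_varcomp <- function(tt, trait = NULL, year = NULL) {
  d <- select_trait(tt, trait, year)
  if (length(unique(d$provenance)) < 2L)
    stop("singular design: need >= 2 provenances")
  d$fam_id <- interaction(d$provenance, d$family, drop = TRUE)
  if (nlevels(d$fam_id) < 2L) stop("need >= 2 families in total")
  d$block <- factor(d$block)
  fit <- suppressMessages(lme4::lmer(
    value ~ block + (1 | provenance) + (1 | fam_id),
    data = d, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  get_vc <- function(g) vc$vcov[vc$grp == g]
  msgs <- fit@optinfo$conv$lme4$messages
  converged <- fit@optinfo$conv$opt == 0 &&
    (is.null(msgs) || !any(grepl("failed to converge", msgs, ignore.case = TRUE)))
  fe <- lme4::fixef(fit)
  blocks <- fe[grepl("^block", names(fe))]
  names(blocks) <- sub("^block", "", names(blocks))
  structure(list(sigma2_P = get_vc("provenance"),
                 sigma2_F = get_vc("fam_id"),
                 sigma2_E = get_vc("Residual"),
                 blocks = blocks,
                 grand_mean = unname(fe["(Intercept)"]),
                 loglik = as.numeric(stats::logLik(fit)),
                 converged = converged,
                 n_obs = nrow(d),
                 n_prov = length(unique(d$provenance)),
                 n_fam = nlevels(d$fam_id),
                 trait = d$trait[1L], year = d$year[1L]),
            class = "variance_components")
}

select_trait <- function(tt, trait, year) {
  need <- c("provenance", "family", "block", "value")
  if (!all(need %in% names(tt)))
    stop("trait table must have columns: ", paste(need, collapse = ", "))
  d <- tt
  if (!"trait" %in% names(d)) d$trait <- "trait"
  if (!"year" %in% names(d)) d$year <- 1L
  if (is.null(trait)) {
    if (length(unique(d$trait)) > 1L) stop("multiple traits present; specify `trait`")
  } else d <- d[d$trait == trait, , drop = FALSE]
  if (is.null(year)) {
    if (length(unique(d$year)) > 1L) stop("multiple years present; specify `year`")
  } else d <- d[d$year == year, , drop = FALSE]
  if (!nrow(d)) stop("no observations for trait ", trait, ", year ", year)
  if (any(!is.finite(d$value))) stop("non-finite trait values")
  d
}

#' @export
print.variance_components <- function(x, ...) {
  cat("REML variance components (", x$trait, ", year ", x$year, "):\n", sep = "")
  cat(sprintf("  sigma2_P = %.4g  sigma2_F = %.4g  sigma2_E = %.4g\n",
              x$sigma2_P, x$sigma2_F, x$sigma2_E))
  cat("  n_obs =", x$n_obs, " converged =", x$converged, "\n")
  invisible(x)
}

#' Q_ST from fitted variance components
#'
#' Q_ST = sigma2_P / (sigma2_P + 8 * sigma2_F) for a half-sib design.
#' When both components are at the zero boundary the ratio is undefined
#' and an error is raised.
#'
#' @param vc a `variance_components` object, or a list with `sigma2_P` and
#'   `sigma2_F`.
#' @return scalar Q_ST in [0, 1].
#' @export
qst_from_varcomp <- function(vc) {
  den <- vc$sigma2_P + 8 * vc$sigma2_F
  if (den <= 0)
    stop("Q_ST undefined: sigma2_P + 8*sigma2_F = 0 (both components at the boundary)")
  vc$sigma2_P / den
}

#' Pairwise Q_ST matrix
#'
#' For every unordered pair of provenances, refits the mixed model on that
#' pair's observations (block coding retained from the full design so block
#' effects stay estimable) and applies the Q_ST formula. Pairs where either
#' member has a single family, where the fit fails, or where both variance
#' components are at the boundary are flagged `NA`.
#'
#' @inheritParams fit_varcomp
#' @return labeled symmetric matrix (class `qst_matrix`) with zero
#'   diagonal; attribute `flags` is a data frame of non-estimable pairs
#'   with reasons, attribute `converged` a logical matrix.
#' @export
pairwise_qst <- function(tt, trait = NULL, year = NULL) {
  d <- select_trait(tt, trait, year)
  provs <- sort(unique(d$provenance))
  if (length(provs) < 2L) stop("need >= 2 provenances")
  m <- matrix(NA_real_, length(provs), length(provs),
              dimnames = list(provs, provs))
  diag(m) <- 0
  conv <- matrix(NA, length(provs), length(provs), dimnames = dimnames(m))
  flags <- list()
  n_fams <- tapply(d$family, d$provenance, function(f) length(unique(f)))
  for (i in seq_along(provs)[-1L]) for (j in seq_len(i - 1L)) {
    pa <- provs[i]; pb <- provs[j]
    if (n_fams[[pa]] < 2L || n_fams[[pb]] < 2L) {
      flags[[length(flags) + 1L]] <- data.frame(
        pop_a = pa, pop_b = pb, reason = "single family: sigma2_F inestimable")
      next
    }
    sub <- d[d$provenance %in% c(pa, pb), , drop = FALSE]
    res <- tryCatch({
      vc <- fit_varcomp(sub)
      list(q = qst_from_varcomp(vc), conv = vc$converged)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      flags[[length(flags) + 1L]] <- data.frame(pop_a = pa, pop_b = pb,
                                                reason = conditionMessage(res))
      next
    }
    m[i, j] <- m[j, i] <- res$q
    conv[i, j] <- conv[j, i] <- res$conv
  }
  structure(m, class = c("qst_matrix", class(m)),
            flags = if (length(flags)) do.call(rbind, flags) else NULL,
            converged = conv)
}

#' Per-year trait means and mean pairwise Q_ST
#'
#' For every trait x year combination present, reports the phenotypic mean
#' and the mean of the off-diagonal pairwise Q_ST entries (NA-flagged pairs
#' excluded).
#'
#' @param tt trait table (long format).
#' @param traits,years optional subsets.
#' @return data frame: `trait`, `year`, `mean_value`, `mean_pairwise_qst`,
#'   `n_pairs_defined`.
#' @export
annual_qst_summary <- function(tt, traits = NULL, years = NULL) {
  if (!"trait" %in% names(tt)) tt$trait <- "trait"
  if (!"year" %in% names(tt)) tt$year <- 1L
  traits <- if (is.null(traits)) unique(tt$trait) else traits
  years <- if (is.null(years)) sort(unique(tt$year)) else years
  rows <- list()
  for (tr in traits) for (yr in years) {
    d <- tt[tt$trait == tr & tt$year == yr, , drop = FALSE]
    if (!nrow(d)) next
    q <- tryCatch(pairwise_qst(d), error = function(e) NULL)
    off <- if (is.null(q)) NA_real_ else q[lower.tri(q)]
    rows[[length(rows) + 1L]] <- data.frame(
      trait = tr, year = yr, mean_value = mean(d$value),
      mean_pairwise_qst = if (all(is.na(off))) NA_real_ else mean(off, na.rm = TRUE),
      n_pairs_defined = sum(!is.na(off)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Read / write trait tables
#'
#' Long-format CSV with columns `individual`, `provenance`, `family`,
#' `block`, `year`, `trait`, `value`.
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_traits <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("provenance", "family", "block", "year", "trait", "value")
  if (!all(need %in% names(df)))
    stop("trait table must have columns: ", paste(need, collapse = ", "))
  df
}

#' @rdname read_traits
#' @param tt trait table data frame.
#' @export
write_traits <- function(tt, path) {
  utils::write.csv(tt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
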