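#' Configuration for common-garden trait simulation
#'
#' Defines the variance structure of a randomized-block half-sib provenance
#' trial: observation = grand mean + fixed block offset + random provenance
#' effect (variance `var_provenance`) + random family-within-provenance
#' effect (variance `var_family`) + residual (variance `var_residual`).
#' Defaults mirror a 22-provenance, 10-block trial with unequal family
#' counts allowed (a vector of 1-26 families per provenance is accepted).
#'
#' @param n_prov number of provenances (>= 2 for downstream fitting).
#' @param families_per_prov families per provenance; scalar or length-
#'   `n_prov` vector.
#' @param n_blocks replicate blocks.
#' @param n_per_family_block individuals per family per block.
#' @param grand_mean trait grand mean (trait units).
#' @param block_effects fixed block offsets, length `n_blocks`; default an
#'   evenly spaced, zero-centred gradient.
#' @param var_provenance,var_family,var_residual variance components
#'   (trait units squared, >= 0).
#' @param mortality fraction of observations removed completely at random
#'   (missing-at-random thinning emulating field mortality).
#' @param seed integer seed.
#' @return object of class `garden_sim_config`.
#' @export
garden_sim_config <- function(n_prov = 22L, families_per_prov = 10L,
                              n_blocks = 10L, n_per_family_block = 5L,
                              grand_mean = 5, block_effects = NULL,
                              var_provenance = 0.3, var_family = 0.05,
                              var_residual = 1, mortality = 0, seed = 1L) {
  stopifnot(n_prov >= 1L, n_blocks >= 1L, n_per_family_block >= 1L,
            var_provenance >= 0, var_family >= 0, var_residual >= 0,
            mortality >= 0, mortality < 1)
  families_per_prov <- as.integer(families_per_prov)
  if (length(families_per_prov) == 1L)
    families_per_prov <- rep(families_per_prov, n_prov)
  if (length(families_per_prov) != n_prov)
    stop("families_per_prov must have length 1 or n_prov (", n_prov, ")")
  if (any(families_per_prov < 1L)) stop("each provenance needs >= 1 family")
  if (is.null(block_effects)) {
    block_effects <- if (n_blocks == 1L) 0 else
      seq(-0.5, 0.5, length.out = n_blocks)
  }
  if (length(block_effects) != n_blocks)
    stop("block_effects must have length n_blocks (", n_blocks, ")")
  structure(list(n_prov = as.integer(n_prov),
                 families_per_prov = families_per_prov,
                 n_blocks = as.integer(n_blocks),
                 n_per_family_block = as.integer(n_per_family_block),
                 grand_mean = grand_mean, block_effects = block_effects,
                 var_provenance = var_provenance, var_family = var_family,
                 var_residual = var_residual, mortality = mortality,
                 seed = as.integer(seed)),
            class = "garden_sim_config")
}

#' True Q_ST implied by a variance configuration
#'
#' Q_ST for a half-sib design: `var_P / (var_P + 8 * var_F)` (family
#' variance is one quarter of the additive variance, hence the factor 8).
#'
#' @param var_provenance,var_family variance components (>= 0, not both 0).
#' @return scalar in [0, 1].
#' @export
true_qst <- function(var_provenance, var_family) {
  den <- var_provenance + 8 * var_family
  if (den <= 0) stop("Q_ST undefined: var_provenance + 8*var_family must be > 0")
  var_provenance / den
}

#' Simulate a common-garden trait table
#'
#' Draws provenance effects ~ N(0, var_provenance), family effects ~
#' N(0, var_family), residuals ~ N(0, var_residual), adds the fixed block
#' offsets, and returns a long-format trait table plus the ground truth.
#' Optional missing-at-random thinning (`mortality`) emulates field
#' mortality; a threshold-liability binary survival trait can be appended
#' with `survival_trait = TRUE` (the indicator is 1 when the latent
#' liability, built from the same effect draws, exceeds the quantile
#' implied by `survival_rate`).
#'
#' @param cfg a `garden_sim_config`.
#' @param trait trait code for the `trait` column (default `"HEIT"`).
#' @param year integer year index for the `year` column.
#' @param survival_trait append a binary SR trait sharing the provenance /
#'   family structure.
#' @param survival_rate overall expected survival when `survival_trait` is
#'   on.
#' @return list of class `garden_sim`: `traits` (data frame `individual`,
#'   `provenance`, `family`, `block`, `year`, `trait`, `value`) and
#'   `truth` (provenance/family effect draws, variance components, true
#'   Q_ST, config).
#' @export
simulate_common_garden <- function(cfg, trait = "HEIT", year = 1L,
                                   survival_trait = FALSE,
                                   survival_rate = 0.7) {
  stopifnot(inherits(cfg, "garden_sim_config"))
  provs <- sprintf("P%02d", seq_len(cfg$n_prov))
  fam_prov <- rep(provs, cfg$families_per_prov)
  fams <- unlist(lapply(cfg$families_per_prov, function(k) sprintf("F%02d", seq_len(k))))
  n_fam <- length(fams)
  res <- with_seed(derive_seed(cfg$seed, "garden"), {
    p_eff <- stats::rnorm(cfg$n_prov, 0, sqrt(cfg$var_provenance))
    f_eff <- stats::rnorm(n_fam, 0, sqrt(cfg$var_family))
    idx_fam <- rep(seq_len(n_fam), each = cfg$n_blocks * cfg$n_per_family_block)
    block <- rep(rep(sprintf("B%02d", seq_len(cfg$n_blocks)),
                     each = cfg$n_per_family_block), times = n_fam)
    n_obs <- length(idx_fam)
    resid <- stats::rnorm(n_obs, 0, sqrt(cfg$var_residual))
    mu_part <- cfg$grand_mean +
      cfg$block_effects[match(block, sprintf("B%02d", seq_len(cfg$n_blocks)))] +
      p_eff[match(fam_prov[idx_fam], provs)] + f_eff[idx_fam]
    value <- mu_part + resid
    df <- data.frame(
      individual = sprintf("i%06d", seq_len(n_obs)),
      provenance = fam_prov[idx_fam],
      family = fams[idx_fam],
      block = block, year = as.integer(year), trait = trait,
      value = value, stringsAsFactors = FALSE)
    if (survival_trait) {
      liab <- mu_part - cfg$grand_mean + resid
      thr <- stats::quantile(liab, probs = 1 - survival_rate, names = FALSE)
      df_sr <- df
      df_sr$trait <- "SR"
      df_sr$value <- as.numeric(liab > thr)
      df <- rbind(df, df_sr)
    }
    if (cfg$mortality > 0) {
      dead <- stats::runif(n_obs) < cfg$mortality
      df <- df[!dead[match(df$individual, sprintf("i%06d", seq_len(n_obs)))], ]
    }
    list(df = df, p_eff = p_eff, f_eff = f_eff)
  })
  truth <- list(provenance_effects = stats::setNames(res$p_eff, provs),
                family_effects = stats::setNames(res$f_eff, paste(fam_prov, fams, sep = ":")),
                var_provenance = cfg$var_provenance,
                var_family = cfg$var_family,
                var_residual = cfg$var_residual,
                true_qst = if (cfg$var_provenance + 8 * cfg$var_family > 0)
                  true_qst(cfg$var_provenance, cfg$var_family) else NA_real_,
                config = cfg)
  structure(list(traits = res$df, truth = truth), class = "garden_sim")
}

#' Write / read the ground-truth sidecar
#'
#' Serializes the true parameters of a simulated dataset to YAML so every
#' simulated table travels with its generating values.
#'
#' @param truth the `truth` element of a `garden_sim` or a plain list.
#' @param path output path.
#' @return `path` invisibly (write); the truth list (read).
#' @export
write_truth <- function(truth, path) {
  if (!is.null(truth$config)) truth$config <- unclass(truth$config)
  conv <- function(x) {
    if (is.list(x)) lapply(x, conv)
    else if (!is.null(names(x))) as.list(x)   # keep names through YAML maps
    else x
  }
  yaml::write_yaml(conv(truth), path, precision = 12L)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) yaml::read_yaml(path)
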