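#' Default pipeline configuration
#'
#' A complete run configuration for [run_pipeline()]: which stages to run,
#' where the inputs come from (paths, or the built-in simulator), the
#' seeds, and the permutation/bootstrap/resample counts. Every stochastic
#' stage derives its own stream from the single `seed`.
#'
#' @param seed global integer seed.
#' @param stages character vector among `"simulate"`, `"popgen"`,
#'   `"quantgen"`, `"matrices"`, `"qstfst"`, `"tree"`.
#' @param n_perm Mantel permutations.
#' @param n_boot NJ bootstrap replicates.
#' @param n_resamples neutrality-test resamples.
#' @param marker,garden,geography optional overrides: lists of arguments to
#'   [marker_sim_config()], [garden_sim_config()] and
#'   [simulate_geography_climate()].
#' @param genotypes_csv,traits_csv,meta_csv,climate_csv input paths used
#'   when `"simulate"` is not among the stages.
#' @return a named list (class `run_config`).
#' @export
run_config <- function(seed = 1L,
                       stages = c("simulate", "popgen", "quantgen",
                                  "matrices", "qstfst", "tree"),
                       n_perm = 999L, n_boot = 200L, n_resamples = 2000L,
                       marker = list(), garden = list(), geography = list(),
                       genotypes_csv = NULL, traits_csv = NULL,
                       meta_csv = NULL, climate_csv = NULL) {
  known <- c("simulate", "popgen", "quantgen", "matrices", "qstfst", "tree")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(seed = as.integer(seed), stages = stages,
                 n_perm = as.integer(n_perm), n_boot = as.integer(n_boot),
                 n_resamples = as.integer(n_resamples),
                 marker = marker, garden = garden, geography = geography,
                 genotypes_csv = genotypes_csv, traits_csv = traits_csv,
                 meta_csv = meta_csv, climate_csv = climate_csv),
            class = "run_config")
}

write_matrix_csv <- function(m, path) {
  df <- data.frame(population = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Read a labeled square matrix CSV
#'
#' First column `population` holds row labels; remaining columns are the
#' matrix, with column names matching the labels.
#'
#' @param path CSV path.
#' @return labeled matrix.
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "double"
  m
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the requested stages in dependency order and writes every
#' report table to `out_dir`: simulated (or loaded) genotype, trait,
#' metadata and climate tables; per-population diversity and its mean row;
#' per-locus and multilocus G_ST with the IBD regression; pairwise F_ST,
#' Nei and geographic distance matrices; Mantel tests; per-trait Q_ST
#' matrices and their correlation table; the Q_ST-F_ST neutrality table;
#' and the NJ tree with bootstrap supports. A `manifest.csv` (file list +
#' config MD5 hash) and `log.txt` (seeds, counts, headline statistics)
#' accompany the tables. Reruns with an identical config are
#' bit-identical.
#'
#' @param config a `run_config`, a list of its arguments, or the path of a
#'   YAML file holding them.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly; headline results as attribute `summary`.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.yml")
  yaml::write_yaml(unclass(config), cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  log <- c(sprintf("run started; config hash %s", cfg_hash),
           sprintf("seed %d; n_perm %d; n_boot %d; n_resamples %d",
                   config$seed, config$n_perm, config$n_boot, config$n_resamples))
  outputs <- character(0)
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    outputs <<- c(outputs, name)
    path
  }
  summary <- list()
  stages <- config$stages

  ## ---- inputs ----
  gt <- traits <- meta <- climate <- NULL
  if ("simulate" %in% stages) {
    mk <- do.call(marker_sim_config,
                  utils::modifyList(list(seed = derive_seed(config$seed, "markers")),
                                    config$marker))
    sim <- simulate_markers(n_pops = mk$n_pops, n_loci = mk$n_loci,
                            n_per_pop = mk$n_per_pop, target_fst = mk$target_fst,
                            seed = mk$seed,
                            ancestral_allele_freqs = mk$ancestral_allele_freqs)
    gt <- sim$genotypes
    gd <- do.call(garden_sim_config,
                  utils::modifyList(list(seed = derive_seed(config$seed, "garden"),
                                         n_prov = mk$n_pops),
                                    config$garden))
    garden <- simulate_common_garden(gd)
    traits <- garden$traits
    if (gd$n_prov == mk$n_pops) {
      ## align provenance labels with the marker populations
      traits$provenance <- gt_populations(gt)[match(traits$provenance,
                                                    sprintf("P%02d", seq_len(gd$n_prov)))]
    }
    geo <- do.call(simulate_geography_climate,
                   utils::modifyList(list(n_pops = mk$n_pops,
                                          seed = derive_seed(config$seed, "geo")),
                                     config$geography))
    meta <- geo$meta; meta$population <- gt_populations(gt)
    climate <- geo$climate; climate$population <- gt_populations(gt)
    emit("genotypes.csv", function(p) write_genotypes(gt, p, "genalex"))
    emit("traits.csv", function(p) write_traits(traits, p))
    emit("population_meta.csv", function(p)
      utils::write.csv(meta, p, row.names = FALSE, quote = FALSE))
    emit("climate.csv", function(p)
      utils::write.csv(climate, p, row.names = FALSE, quote = FALSE))
    emit("truth.yml", function(p)
      write_truth(c(garden$truth[setdiff(names(garden$truth), "config")],
                    list(target_fst = mk$target_fst)), p))
    log <- c(log, sprintf("simulated %d pops x %d loci; garden %d provenances",
                          mk$n_pops, mk$n_loci, gd$n_prov))
  } else {
    if (!is.null(config$genotypes_csv)) gt <- read_genotypes(config$genotypes_csv)
    if (!is.null(config$traits_csv)) traits <- read_traits(config$traits_csv)
    if (!is.null(config$meta_csv)) meta <- read_population_meta(config$meta_csv)
    if (!is.null(config$climate_csv))
      climate <- utils::read.csv(config$climate_csv, check.names = FALSE)
  }

  need <- function(x, what, stage)
    if (is.null(x)) stop("stage '", stage, "' needs ", what,
                         ": provide an input path or enable the simulate stage")

  ## ---- popgen ----
  dstats <- diff_res <- fst_m <- nei_m <- NULL
  if ("popgen" %in% stages) {
    need(gt, "genotypes", "popgen")
    dstats <- diversity_stats(gt)
    emit("diversity_population.csv", function(p)
      utils::write.csv(dstats$by_population, p, row.names = FALSE, quote = FALSE))
    emit("diversity_mean.csv", function(p)
      utils::write.csv(aggregate_diversity(dstats), p, row.names = FALSE, quote = FALSE))
    diff_res <- suppressWarnings(gst(gt))
    emit("differentiation_loci.csv", function(p)
      utils::write.csv(rbind(diff_res$per_locus,
                             data.frame(locus = "multilocus", hs = diff_res$hs_mean,
                                        ht = diff_res$ht_mean, gst = diff_res$multilocus)),
                       p, row.names = FALSE, quote = FALSE))
    fst_m <- pairwise_fst(gt)
    emit("pairwise_fst.csv", function(p) write_matrix_csv(fst_m, p))
    nei_m <- suppressWarnings(nei_distance(gt))
    emit("nei_distance.csv", function(p) write_matrix_csv(nei_m, p))
    summary$multilocus_gst <- diff_res$multilocus
    summary$multilocus_theta <- as.numeric(wc_theta(gt))
    log <- c(log, sprintf("multilocus G_ST %.4f; WC theta %.4f",
                          summary$multilocus_gst, summary$multilocus_theta))
  }

  ## ---- quantgen ----
  qst_mats <- list()
  if ("quantgen" %in% stages) {
    need(traits, "a trait table", "quantgen")
    combos <- unique(traits[, c("trait", "year")])
    vc_rows <- list()
    for (k in seq_len(nrow(combos))) {
      tr <- combos$trait[k]; yr <- combos$year[k]
      vc <- fit_varcomp(traits, tr, yr)
      vc_rows[[k]] <- data.frame(trait = tr, year = yr,
                                 sigma2_P = vc$sigma2_P, sigma2_F = vc$sigma2_F,
                                 sigma2_E = vc$sigma2_E,
                                 qst = tryCatch(qst_from_varcomp(vc),
                                                error = function(e) NA_real_),
                                 converged = vc$converged, n_obs = vc$n_obs)
      qm <- pairwise_qst(traits, tr, yr)
      qst_mats[[paste0(tr, yr)]] <- qm
      emit(sprintf("qst_%s_%s.csv", tr, yr),
           function(p) write_matrix_csv(unclass(qm), p))
    }
    emit("variance_components.csv", function(p)
      utils::write.csv(do.call(rbind, vc_rows), p, row.names = FALSE, quote = FALSE))
    emit("annual_summary.csv", function(p)
      utils::write.csv(annual_qst_summary(traits), p, row.names = FALSE, quote = FALSE))
    summary$qst <- vc_rows[[1L]]$qst
    log <- c(log, sprintf("global Q_ST (%s, year %s): %.4f",
                          combos$trait[1L], combos$year[1L], summary$qst))
  }

  ## ---- matrices ----
  if ("matrices" %in% stages) {
    need(meta, "population metadata", "matrices")
    geo_m <- geographic_distance_matrix(meta)
    emit("geo_distance.csv", function(p) write_matrix_csv(geo_m$distance, p))
    mantel_rows <- list()
    if (!is.null(fst_m)) {
      mr <- mantel(pmax(fst_m, 0), geo_m$distance, n_perm = config$n_perm,
                   seed = derive_seed(config$seed, "mantel_fst_geo"))
      mantel_rows[["fst_vs_geography"]] <- mr
      ibd <- ibd_regression(pmax(fst_m, 0), geo_m$distance,
                            n_perm = config$n_perm,
                            seed = derive_seed(config$seed, "ibd"))
      emit("ibd_regression.csv", function(p)
        utils::write.csv(data.frame(a = ibd$a, b = ibd$b, r = ibd$r, p = ibd$p,
                                    n_pairs = ibd$n_pairs),
                         p, row.names = FALSE, quote = FALSE))
      summary$mantel_r_fst_geo <- mr$r
      log <- c(log, sprintf("Mantel F_ST~geography: r %.4f p %.4g (seed %d)",
                            mr$r, mr$p, config$seed))
    }
    if (!is.null(climate)) {
      clim_mats <- climate_distance_matrices(climate)
      pred <- c(list(geography = geo_m$distance), clim_mats)
      if (length(qst_mats)) {
        qct <- qst_correlation_table(lapply(qst_mats, unclass), pred,
                                     n_perm = config$n_perm,
                                     seed = derive_seed(config$seed, "qct"))
        emit("qst_correlations.csv", function(p)
          utils::write.csv(qct, p, row.names = FALSE, quote = FALSE))
      }
    }
    if (length(mantel_rows)) {
      emit("mantel.csv", function(p)
        utils::write.csv(do.call(rbind, lapply(names(mantel_rows), function(nm) {
          x <- mantel_rows[[nm]]
          data.frame(comparison = nm, r = x$r, p = x$p, n_perm = x$n_perm,
                     tail = x$tail)
        })), p, row.names = FALSE, quote = FALSE))
    }
  }

  ## ---- qstfst ----
  if ("qstfst" %in% stages) {
    need(gt, "genotypes", "qstfst"); need(traits, "a trait table", "qstfst")
    combos <- unique(traits[, c("trait", "year")])
    results <- list()
    for (k in seq_len(nrow(combos))) {
      res <- tryCatch(
        qst_fst_test(traits, gt, combos$trait[k], combos$year[k],
                     n_resamples = config$n_resamples,
                     seed = derive_seed(config$seed, paste0("qstfst", k))),
        error = function(e) e)
      if (!inherits(res, "error")) results[[length(results) + 1L]] <- res
      else log <- c(log, sprintf("qstfst skipped %s%s: %s", combos$trait[k],
                                 combos$year[k], conditionMessage(res)))
    }
    if (length(results)) {
      tab <- qstfst_table(results)
      emit("qstfst.csv", function(p)
        utils::write.csv(tab, p, row.names = FALSE, quote = FALSE))
      summary$qstfst_diff <- tab$qst_fst_diff[1L]
      log <- c(log, sprintf("Q_ST-F_ST (%s): diff %.4f p %.4g",
                            tab$trait_code[1L], tab$qst_fst_diff[1L],
                            tab$p_two_tailed[1L]))
    }
  }

  ## ---- tree ----
  if ("tree" %in% stages) {
    need(gt, "genotypes", "tree")
    tr <- bootstrap_support(gt, n_boot = config$n_boot,
                            seed = derive_seed(config$seed, "tree"))
    emit("tree.nwk", function(p) write_newick(tr, p))
    log <- c(log, sprintf("NJ tree with %d-replicate locus bootstrap", config$n_boot))
  }

  utils::write.csv(data.frame(file = c("config.yml", outputs),
                              config_hash = cfg_hash),
                   file.path(out_dir, "manifest.csv"), row.names = FALSE,
                   quote = FALSE)
  writeLines(log, file.path(out_dir, "log.txt"))
  invisible(structure(out_dir, summary = summary))
}

#' Summarize a completed pipeline run
#'
#' Reads the tables a run produced and writes `summary.txt`: a
#' diversity section (per-population means), a differentiation/IBD
#' section, a Q_ST-correlation section, and a neutrality-test section.
#' Sections whose tables are absent are marked skipped; an incomplete run
#' lists its missing stages.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return the summary lines, invisibly; also written to
#'   `run_dir/summary.txt`.
#' @export
report <- function(run_dir) {
  if (!dir.exists(run_dir)) stop("no such run directory: ", run_dir)
  have <- function(f) file.exists(file.path(run_dir, f))
  lines <- c("Pipeline run summary", strrep("=", 40))
  if (have("manifest.csv")) {
    mf <- utils::read.csv(file.path(run_dir, "manifest.csv"))
    lines <- c(lines, paste("config hash:", mf$config_hash[1L]))
  }
  section <- function(title, file, render) {
    if (!have(file)) return(c("", paste0(title, ": skipped (", file, " absent)")))
    c("", paste0(title, ":"), render(utils::read.csv(file.path(run_dir, file),
                                                     check.names = FALSE)))
  }
  lines <- c(lines,
    section("Diversity (per-population means)", "diversity_mean.csv", function(d)
      sprintf("  %s = %.3f +- %.3f", d$stat, d$mean, d$sd)),
    section("Differentiation per locus", "differentiation_loci.csv", function(d)
      c(sprintf("  %s: G_ST = %.4f", d$locus, d$gst))),
    section("IBD regression", "ibd_regression.csv", function(d)
      sprintf("  a = %.4f, b = %.4f, r = %.4f, p = %.4g", d$a, d$b, d$r, d$p)),
    section("Mantel tests", "mantel.csv", function(d)
      sprintf("  %s: r = %.4f, p = %.4g (%d perms)", d$comparison, d$r, d$p, d$n_perm)),
    section("Q_ST correlations", "qst_correlations.csv", function(d)
      sprintf("  %s ~ %s: r = %.3f %s", d$trait, d$predictor, d$r, d$signif)),
    section("Q_ST-F_ST neutrality tests", "qstfst.csv", function(d)
      sprintf("  %s: diff = %.4f [%.4f, %.4f] %s (%s)", d$trait_code,
              d$qst_fst_diff, d$crit_lo_2.5, d$crit_hi_97.5, d$signif, d$direction)))
  writeLines(lines, file.path(run_dir, "summary.txt"))
  invisible(lines)
}
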