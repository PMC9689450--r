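balanced_garden <- function(seed = 1, sP = 0.4, sF = 0.1, sE = 1) {
  cfg <- garden_sim_config(n_prov = 6, families_per_prov = 4, n_blocks = 3,
                           n_per_family_block = 3, var_provenance = sP,
                           var_family = sF, var_residual = sE, seed = seed)
  simulate_common_garden(cfg)$traits
}

test_that("REML matches the Henderson method-III closed form on balanced data", {
  for (seed in c(4, 9)) {
    tt <- balanced_garden(seed)
    vc <- fit_varcomp(tt)
    or <- henderson_varcomp(tt)
    ## interior solutions only: boundary projection differs by construction
    if (or$sigma2_P > 1e-6 && or$sigma2_F > 1e-6) {
      expect_equal(vc$sigma2_P, or$sigma2_P, tolerance = 1e-4)
      expect_equal(vc$sigma2_F, or$sigma2_F, tolerance = 1e-4)
      expect_equal(vc$sigma2_E, or$sigma2_E, tolerance = 1e-4)
    }
    expect_true(vc$converged)
  }
})

test_that("zero provenance variance lands on the boundary and singular designs error", {
  tt <- balanced_garden(seed = 5, sP = 0, sF = 0.2)
  vc <- fit_varcomp(tt)
  expect_lt(vc$sigma2_P, 0.02)
  one_prov <- tt[tt$provenance == "P01", ]
  expect_error(fit_varcomp(one_prov), "2 provenances")
})

test_that("Q_ST is the half-sib variance ratio with its boundary cases", {
  expect_equal(qst_from_varcomp(list(sigma2_P = 0, sigma2_F = 0.3)), 0)
  expect_equal(qst_from_varcomp(list(sigma2_P = 0.7, sigma2_F = 0)), 1)
  expect_equal(qst_from_varcomp(list(sigma2_P = 0.8, sigma2_F = 0.1)), 0.5)
  expect_error(qst_from_varcomp(list(sigma2_P = 0, sigma2_F = 0)), "undefined")
})

test_that("Q_ST is invariant under affine transformation of the trait", {
  tt <- balanced_garden(seed = 12)
  q1 <- qst_from_varcomp(fit_varcomp(tt))
  tt2 <- tt
  tt2$value <- -3.7 * tt2$value + 11
  q2 <- qst_from_varcomp(fit_varcomp(tt2))
  expect_equal(q1, q2, tolerance = 1e-6)
})

test_that("pairwise Q_ST produces all pairs and flags single-family provenances", {
  tt <- balanced_garden(seed = 3)
  qm <- pairwise_qst(tt)
  expect_equal(dim(qm), c(6, 6))
  expect_equal(sum(!is.na(qm[lower.tri(qm)])), 15)  # choose(6, 2)
  expect_equal(unclass(qm), t(unclass(qm)))
  expect_true(all(qm[!is.na(qm)] >= 0 & qm[!is.na(qm)] <= 1))
  ## make P01 single-family: its pairs must be flagged
  tt_sf <- tt[!(tt$provenance == "P01" & tt$family != "F01"), ]
  qm2 <- pairwise_qst(tt_sf)
  expect_true(all(is.na(qm2["P01", -1])))
  flags <- attr(qm2, "flags")
  expect_true(any(grepl("single family", flags$reason)))
})

test_that("provenances sharing one effect draw give near-zero pairwise Q_ST", {
  tt <- balanced_garden(seed = 21, sP = 0.6)
  ## clone P01's provenance effect onto P02 by shifting P02's values
  eff <- tapply(tt$value, tt$provenance, mean)
  tt$value[tt$provenance == "P02"] <-
    tt$value[tt$provenance == "P02"] - (eff[["P02"]] - eff[["P01"]])
  qm <- pairwise_qst(tt)
  expect_lt(qm["P01", "P02"], 0.15)
})

test_that("annual summary tracks a constructed monotone Q_ST scenario", {
  tts <- lapply(1:3, function(yr) {
    cfg <- garden_sim_config(n_prov = 5, families_per_prov = 3, n_blocks = 2,
                             n_per_family_block = 3,
                             var_provenance = c(0.02, 0.4, 2.5)[yr],
                             var_family = 0.1, var_residual = 0.5,
                             seed = 40 + yr)
    g <- simulate_common_garden(cfg, year = yr)
    g$traits
  })
  tt <- do.call(rbind, tts)
  s <- annual_qst_summary(tt)
  expect_equal(nrow(s), 3)
  expect_true(all(diff(s$mean_pairwise_qst) > 0))
  ## single-pair dataset: summary mean equals that pair's value
  two <- tts[[2]][tts[[2]]$provenance %in% c("P01", "P02"), ]
  s2 <- annual_qst_summary(two)
  expect_equal(s2$mean_pairwise_qst, pairwise_qst(two)["P01", "P02"])
})

test_that("trait tables round-trip through CSV", {
  tt <- balanced_garden(seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_traits(tt, path)
  back <- read_traits(path)
  expect_equal(back$value, tt$value, tolerance = 1e-12)
  expect_identical(back$provenance, tt$provenance)
})
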