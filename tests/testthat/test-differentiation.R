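test_that("G_ST hits its boundary cases", {
  ## two populations fixed for different alleles -> G_ST = 1
  gt <- make_gt(list(A = list(L1 = pairs_mat(1, 1, 1, 1, 1, 1)),
                     B = list(L1 = pairs_mat(2, 2, 2, 2, 2, 2))))
  expect_equal(gst(gt)$multilocus, 1)
  ## identical data in both populations -> G_ST ~ 0
  block <- pairs_mat(1, 2, 1, 1, 2, 2, 1, 2, 1, 2, 2, 2, 1, 1, 1, 2)
  block <- rbind(block, block, block)   # n = 24 per population
  gt2 <- make_gt(list(A = list(L1 = block), B = list(L1 = block)))
  expect_lt(abs(gst(gt2)$multilocus), 0.02)
  ## globally monomorphic locus excluded with warning
  gt3 <- make_gt(list(A = list(L1 = pairs_mat(1, 1, 1, 2), L2 = pairs_mat(3, 3, 3, 3)),
                      B = list(L1 = pairs_mat(2, 2, 1, 2), L2 = pairs_mat(3, 3, 3, 3))))
  expect_warning(res <- gst(gt3), "monomorphic")
  expect_true(is.na(res$per_locus$gst[res$per_locus$locus == "L2"]))
})

test_that("Nei-Chesser G_ST matches the hand-coded estimator on a toy table", {
  gt <- make_gt(list(
    A = list(L1 = pairs_mat(1, 1, 1, 2, 1, 2, 2, 2, 1, 1)),
    B = list(L1 = pairs_mat(2, 2, 2, 2, 1, 2, 2, 2))))
  res <- gst(gt)
  or <- nc_gst_oracle(
    freq_list = list(c("1" = 6 / 10, "2" = 4 / 10), c("1" = 1 / 8, "2" = 7 / 8)),
    n_vec = c(5, 4), ho_vec = c(2 / 5, 1 / 4))
  expect_equal(res$per_locus$hs, or$hs, tolerance = 1e-12)
  expect_equal(res$per_locus$ht, or$ht, tolerance = 1e-12)
  expect_equal(res$multilocus, or$gst, tolerance = 1e-12)
})

test_that("multilocus G_ST is invariant to locus order and whole-panel duplication", {
  sim <- simulate_markers(n_pops = 5, n_loci = 6, n_per_pop = 10,
                          target_fst = 0.1, seed = 21)
  gt <- sim$genotypes
  g1 <- gst(gt)$multilocus
  g2 <- gst(gt_subset(gt, loci = rev(gt_loci(gt))))$multilocus
  expect_equal(g1, g2)
  ## duplicate the entire locus panel under new names
  loci <- gt_loci(gt)
  al <- c(lapply(loci, function(l) cbind(gt[[paste0(l, "_1")]], gt[[paste0(l, "_2")]])),
          lapply(loci, function(l) cbind(gt[[paste0(l, "_1")]], gt[[paste0(l, "_2")]])))
  names(al) <- c(loci, paste0(loci, "bis"))
  gt_dup <- genotype_table(gt$individual, gt$population, al)
  expect_equal(gst(gt_dup)$multilocus, g1)
})

test_that("Weir-Cockerham theta matches the scalar oracle and hits boundaries", {
  gt <- make_gt(list(
    A = list(L1 = pairs_mat(1, 2, 1, 1, 2, 2, 1, 2),
             L2 = pairs_mat(3, 3, 3, 4, 4, 4, 3, 3)),
    B = list(L1 = pairs_mat(2, 2, 2, 2, 1, 2),
             L2 = pairs_mat(4, 4, 3, 4, 4, 4))))
  expect_equal(as.numeric(wc_theta(gt)), wc_theta_oracle(gt), tolerance = 1e-12)
  expect_equal(pairwise_fst(gt)["A", "B"], wc_theta_oracle(gt), tolerance = 1e-12)
  ## fixed differences at all loci -> theta = 1
  gt_fix <- make_gt(list(A = list(L1 = pairs_mat(1, 1, 1, 1, 1, 1)),
                         B = list(L1 = pairs_mat(2, 2, 2, 2, 2, 2))))
  expect_equal(as.numeric(wc_theta(gt_fix)), 1)
  ## duplicated population -> theta <= 0, truncated to 0 on request
  block <- pairs_mat(1, 2, 1, 1, 2, 2, 1, 2, 2, 2)
  gt_dup <- make_gt(list(A = list(L1 = block), B = list(L1 = block)))
  expect_lte(pairwise_fst(gt_dup)["A", "B"], 0)
  expect_equal(pairwise_fst(gt_dup, truncate = TRUE)["A", "B"], 0)
})

test_that("pairwise theta matrices are symmetric with zero diagonal", {
  sim <- simulate_markers(n_pops = 6, n_loci = 5, n_per_pop = 8,
                          target_fst = 0.15, seed = 8)
  m <- pairwise_fst(sim$genotypes)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 6))
})

test_that("per-locus G_ST and per-locus theta agree in rank order on island-model data", {
  sim <- simulate_markers(n_pops = 12, n_loci = 15, n_per_pop = 15,
                          target_fst = 0.1, seed = 33)
  g <- gst(sim$genotypes)$per_locus$gst
  comp <- attr(wc_theta(sim$genotypes), "components")
  th <- comp[, "a"] / comp[, "abc"]
  expect_gt(cor(g, th, method = "spearman"), 0.8)
})

test_that("Nei distance matches the formula oracle and flags degenerate pairs", {
  gt <- make_gt(list(
    A = list(L1 = pairs_mat(1, 1, 1, 2, 2, 2, 1, 1),
             L2 = pairs_mat(3, 4, 3, 3, 4, 4, 3, 4)),
    B = list(L1 = pairs_mat(2, 2, 1, 2, 2, 2, 2, 2),
             L2 = pairs_mat(3, 3, 3, 3, 3, 4, 3, 3))))
  af <- allele_frequencies(gt)
  D <- nei_distance(gt)
  or <- nei_d_oracle(
    fx = list(L1 = c("1" = af$freq$L1["A", "1"], "2" = af$freq$L1["A", "2"]),
              L2 = c("3" = af$freq$L2["A", "3"], "4" = af$freq$L2["A", "4"])),
    fy = list(L1 = c("1" = af$freq$L1["B", "1"], "2" = af$freq$L1["B", "2"]),
              L2 = c("3" = af$freq$L2["B", "3"], "4" = af$freq$L2["B", "4"])))
  expect_equal(D["A", "B"], or, tolerance = 1e-12)
  ## identical frequencies -> 0
  block <- pairs_mat(1, 2, 1, 1, 2, 2)
  gt_same <- make_gt(list(A = list(L1 = block), B = list(L1 = block)))
  expect_equal(nei_distance(gt_same)["A", "B"], 0)
  ## fixed differences -> infinite, with warning
  gt_fix <- make_gt(list(A = list(L1 = pairs_mat(1, 1, 1, 1)),
                         B = list(L1 = pairs_mat(2, 2, 2, 2))))
  expect_warning(Dfix <- nei_distance(gt_fix), "Inf")
  expect_true(is.infinite(Dfix["A", "B"]))
})
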