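test_that("three-taxon NJ solves the closed-form branch lengths", {
  dm <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(dm)
  pl <- tree_path_matrix(tr)
  expect_equal(pl["A", "B"], 2)
  expect_equal(pl["A", "C"], 4)
  expect_equal(pl["B", "C"], 4)
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[["A"]], 1)
  expect_equal(len[["B"]], 1)
  expect_equal(len[["C"]], 3)
})

test_that("NJ exactly inverts additive matrices and ignores label order", {
  ## additive matrix from tree ((A:1,B:2):1,C:3,D:4)
  ref <- read_newick("((A:1,B:2):1,C:3,D:4);")
  dm <- tree_path_matrix(ref)
  tr <- neighbor_joining(dm)
  expect_equal(tree_path_matrix(tr)[rownames(dm), colnames(dm)], dm,
               tolerance = 1e-12)
  pp <- c(3, 1, 4, 2)
  tr2 <- neighbor_joining(dm[pp, pp])
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2)), 0,
               ignore_attr = TRUE)
})

test_that("degenerate inputs are handled: identical rows and infinities", {
  dm <- matrix(c(0, 0, 3, 0, 0, 3, 3, 3, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(dm)
  pl <- tree_path_matrix(tr)
  expect_equal(pl["a", "b"], 0, tolerance = 1e-12)
  expect_true(all(tr$edge.length >= 0))
  dm[1, 2] <- dm[2, 1] <- Inf
  expect_error(neighbor_joining(dm), "cap")
})

test_that("Newick writing quotes metacharacter labels and round-trips", {
  dm <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
               dimnames = list(c("pop 1060", "B", "C"), c("pop 1060", "B", "C")))
  tr <- neighbor_joining(dm)
  txt <- write_newick(tr)
  expect_match(txt, "'pop 1060'", fixed = TRUE)
  back <- read_newick(txt)
  expect_setequal(back$tip.label, c("pop 1060", "B", "C"))
  expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-12)
  ## file round-trip
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  expect_equal(sort(read_newick(path)$edge.length), sort(tr$edge.length),
               tolerance = 1e-12)
})

test_that("identical locus copies give unit bootstrap support everywhere", {
  sim <- simulate_markers(n_pops = 6, n_loci = 1, n_per_pop = 12,
                          target_fst = 0.15, seed = 2)
  gt <- sim$genotypes
  a <- cbind(gt$L01_1, gt$L01_2)
  al <- setNames(lapply(1:5, function(i) a), paste0("L", 1:5))
  gt5 <- genotype_table(gt$individual, gt$population, al)
  tr <- bootstrap_support(gt5, n_boot = 50, seed = 3)
  sup <- as.numeric(tr$node.label[tr$node.label != ""])
  expect_true(all(sup == 1))
})

test_that("bootstrap supports are deterministic and stable across seeds", {
  sim <- simulate_markers(n_pops = 10, n_loci = 15, n_per_pop = 15,
                          target_fst = 0.15, seed = 14)
  t1 <- bootstrap_support(sim$genotypes, n_boot = 1000, seed = 5)
  t1b <- bootstrap_support(sim$genotypes, n_boot = 1000, seed = 5)
  expect_identical(t1$node.label, t1b$node.label)
  t2 <- bootstrap_support(sim$genotypes, n_boot = 1000, seed = 6)
  s1 <- as.numeric(t1$node.label[t1$node.label != ""])
  s2 <- as.numeric(t2$node.label[t2$node.label != ""])
  ## supports re-estimated under a new bootstrap stream agree to Monte-Carlo
  ## accuracy: on average within 0.05, never beyond twice that
  expect_lte(mean(abs(s1 - s2)), 0.05)
  expect_lte(max(abs(s1 - s2)), 0.10)
  expect_error(bootstrap_support(gt_subset(sim$genotypes,
                                           loci = gt_loci(sim$genotypes)[1]),
                                 n_boot = 10), ">= 2 loci")
})

test_that("Evanno delta-K locates a constructed kink and flags degenerate runs", {
  ## linear mean L(K): all second differences zero
  runs_lin <- data.frame(K = rep(1:4, each = 3),
                         lnP = rep(c(-100, -90, -80, -70), each = 3) +
                           rep(c(-0.5, 0, 0.5), times = 4))
  tab <- evanno_delta_k(runs_lin)
  expect_equal(tab$delta_k[2:3], c(0, 0))
  ## single kink at K = 2
  mu <- c(-200, -120, -115, -112, -110)
  set.seed(1)
  runs <- data.frame(K = rep(1:5, each = 4),
                     lnP = rep(mu, each = 4) + rnorm(20, 0, 0.8))
  tab2 <- evanno_delta_k(runs)
  expect_equal(attr(tab2, "best_k"), 2L)
  ## zero SD at a K -> flagged NA
  runs0 <- data.frame(K = rep(1:3, each = 2), lnP = c(-10, -10, -8, -8, -7, -7))
  tab3 <- evanno_delta_k(runs0)
  expect_true(is.na(tab3$delta_k[2]))
  expect_equal(attr(tab3, "n_flagged_sd0"), 1L)
  expect_error(evanno_delta_k(data.frame(K = rep(1:2, each = 2), lnP = rnorm(4))),
               ">= 3")
  expect_error(evanno_delta_k(data.frame(K = rep(c(1, 3, 5), each = 2), lnP = rnorm(6))),
               "consecutive")
})
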