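sym_mat <- function(v, labels) {
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[lower.tri(m)] <- v
  m + t(m)
}

test_that("Mantel r hits +-1 on identical and reflected matrices", {
  labs <- letters[1:6]
  set.seed(1)
  mA <- sym_mat(runif(15), labs)
  expect_equal(mantel(mA, mA, n_perm = 99, seed = 1)$r, 1)
  refl <- 5 - mA; diag(refl) <- 0
  expect_equal(mantel(mA, refl, n_perm = 99, seed = 1)$r, -1)
})

test_that("Mantel p matches exhaustive evaluation over all 4! relabelings", {
  labs <- LETTERS[1:4]
  set.seed(7)
  mA <- sym_mat(c(1, 2, 3, 4, 5, 6), labs)
  mB <- sym_mat(c(1.2, 2.3, 2.6, 4.4, 4.9, 6.5), labs)
  p_ex <- mantel_exhaustive_p(mA, mB)
  res <- mantel(mA, mB, n_perm = 9999, seed = 5)
  expect_lt(abs(res$p - p_ex), 0.02)
  p_ex2 <- mantel_exhaustive_p(mA, mB, tail = "two_sided")
  res2 <- mantel(mA, mB, n_perm = 9999, seed = 5, tail = "two_sided")
  expect_lt(abs(res2$p - p_ex2), 0.02)
})

test_that("Mantel validates labels, constant triangles and permutation counts", {
  labs <- letters[1:4]
  mA <- sym_mat(1:6, labs)
  mBad <- sym_mat(1:6, LETTERS[1:4])
  expect_error(mantel(mA, mBad, n_perm = 99), "labels")
  expect_error(mantel(mA, sym_mat(rep(2, 6), labs), n_perm = 99), "constant")
  expect_error(mantel(mA, mA, n_perm = 9), ">= 99")
})

test_that("Mantel statistics are invariant to joint relabeling", {
  labs <- letters[1:8]
  set.seed(3)
  mA <- sym_mat(runif(28), labs)
  mB <- sym_mat(runif(28) + 0.5 * mA[lower.tri(mA)], labs)
  res <- mantel(mA, mB, n_perm = 999, seed = 2)
  pp <- c(3, 1, 4, 2, 8, 6, 5, 7)
  res2 <- mantel(mA[pp, pp], mB[pp, pp], n_perm = 999, seed = 2)
  expect_equal(res$r, res2$r, tolerance = 1e-12)
  expect_equal(res$p, res2$p, tolerance = 0.05)
})

test_that("the in-package Mantel test agrees with vegan on the same matrices", {
  skip_if_not_installed("vegan")
  labs <- letters[1:10]
  set.seed(11)
  mA <- sym_mat(runif(45), labs)
  mB <- sym_mat(runif(45) + 0.6 * mA[lower.tri(mA)], labs)
  ours <- mantel(mA, mB, n_perm = 9999, seed = 4)
  vg <- vegan::mantel(as.dist(mA), as.dist(mB), permutations = 9999)
  expect_equal(ours$r, unname(vg$statistic), tolerance = 1e-12)
  expect_lt(abs(ours$p - vg$signif), 0.02)
})

test_that("Mantel type-I error is near nominal under the null", {
  n_rep <- 400
  rej <- 0L
  set.seed(99)
  for (i in seq_len(n_rep)) {
    mA <- sym_mat(runif(105), letters[1:15])
    mB <- sym_mat(runif(105), letters[1:15])
    p <- mantel(mA, mB, n_perm = 199, seed = i)$p
    if (p < 0.05) rej <- rej + 1L
  }
  rate <- rej / n_rep
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.08)
})

test_that("IBD regression recovers constructed coefficients exactly", {
  labs <- sprintf("p%02d", 1:8)
  set.seed(5)
  d <- sym_mat(exp(runif(28, 10, 14.5)), labs)
  a <- -0.0353; b <- 0.0063
  y <- a + b * log(d)
  x <- y / (1 + y)          # so that x/(1-x) = a + b ln d
  diag(x) <- 0
  res <- ibd_regression(x, d, n_perm = 99, seed = 1)
  expect_equal(res$a, a, tolerance = 1e-10)
  expect_equal(res$b, b, tolerance = 1e-10)
  expect_equal(res$r, 1, tolerance = 1e-10)
  ## flat construction: slope 0, undefined r flagged
  xf <- sym_mat(rep(0.05 / 1.05, 28), labs)
  res0 <- ibd_regression(xf, d, n_perm = 99, seed = 1)
  expect_equal(res0$b, 0, tolerance = 1e-12)
  expect_true(is.na(res0$r))
  ## differentiation at 1 is an error
  x1 <- x; x1[2, 1] <- x1[1, 2] <- 1
  expect_error(ibd_regression(x1, d), "linearization")
})

test_that("IBD permutation p is roughly uniform under a permuted-label null", {
  labs <- sprintf("p%02d", 1:10)
  set.seed(8)
  ps <- vapply(1:60, function(i) {
    d <- sym_mat(exp(runif(45, 10, 14)), labs)
    x <- sym_mat(runif(45, 0.01, 0.2), labs)
    ibd_regression(x, d, n_perm = 99, seed = i)$p
  }, numeric(1))
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_gt(mean(ps < 0.25), 0.1)   # spread, not clustered at one end
  expect_gt(mean(ps > 0.75), 0.1)
})

test_that("matrix correlation honours exact linear relations and the null", {
  labs <- letters[1:7]
  set.seed(2)
  mA <- sym_mat(runif(21), labs)
  mB <- 2 * mA + 3; diag(mB) <- 0
  expect_equal(correlate_matrices(mA, mB, n_perm = 99, seed = 1)$r, 1)
  rs <- vapply(1:100, function(i) {
    m1 <- sym_mat(runif(21), labs)
    m2 <- sym_mat(runif(21), labs)
    correlate_matrices(m1, m2, method = "parametric")$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.06)
})

test_that("the Q_ST correlation table has the expected shape and star convention", {
  labs <- letters[1:6]
  set.seed(4)
  qs <- lapply(1:3, function(i) sym_mat(runif(15), labs))
  names(qs) <- paste0("HEIT", 1:3)
  preds <- lapply(1:4, function(i) sym_mat(runif(15), labs))
  names(preds) <- paste0("clim", 1:4)
  tab <- qst_correlation_table(qs, preds, n_perm = 99, seed = 2)
  expect_equal(nrow(tab), 12)
  expect_setequal(unique(tab$trait), names(qs))
  ## a matrix against itself: r = 1
  self <- qst_correlation_table(qs[1], qs[1], n_perm = 99, seed = 3)
  expect_equal(self$r, 1)
  ## star conventions
  expect_equal(p_stars(c(0.2, 0.03, 0.004, 0.0004)), c("ns", "*", "**", "***"))
  expect_equal(p_stars(0.0004, max_stars = 2), "**")
})
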