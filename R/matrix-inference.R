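## Shared validation for labeled symmetric matrices.
check_dist_pair <- function(mA, mB, tol = 1e-8) {
  if (!is.matrix(mA) || !is.matrix(mB)) stop("inputs must be matrices")
  if (is.null(rownames(mA)) || is.null(rownames(mB)))
    stop("matrices must carry population labels")
  if (!identical(dim(mA), dim(mB)) || !identical(rownames(mA), rownames(mB)))
    stop("matrix labels do not match")
  if (max(abs(mA - t(mA)), na.rm = TRUE) > tol ||
      max(abs(mB - t(mB)), na.rm = TRUE) > tol)
    stop("matrices must be symmetric")
  invisible(TRUE)
}

#' Mantel permutation test
#'
#' Pearson correlation of the lower triangles of two labeled symmetric
#' matrices, with significance from joint row-and-column permutations of
#' one matrix. p = (1 + number of permuted r at least as extreme as the
#' observed r) / (n_perm + 1); "as extreme" means `>=` for the default
#' one-sided positive tail, `|r*| >= |r|` for the two-sided tail.
#' Cells that are `NA` in either matrix are pairwise-deleted; the retained
#' pair count is always reported.
#'
#' @param mA,mB labeled symmetric matrices with matching labels.
#' @param n_perm number of permutations (>= 99; the field's customary
#'   default is 10,000).
#' @param seed integer seed for the permutation stream.
#' @param tail `"one_sided_positive"` or `"two_sided"`.
#' @return object of class `mantel_result`: list with `r`, `p`, `n_perm`,
#'   `tail`, `seed`, `n_pairs`.
#' @export
mantel <- function(mA, mB, n_perm = 10000L, seed = NULL,
                   tail = c("one_sided_positive", "two_sided")) {
  tail <- match.arg(tail)
  check_dist_pair(mA, mB)
  if (n_perm < 99L) stop("n_perm must be >= 99")
  lt <- lower.tri(mA)
  keep <- lt & !is.na(mA) & !is.na(mB)
  xa <- mA[keep]
  if (stats::sd(xa) == 0 || stats::sd(mB[keep]) == 0)
    stop("all-constant lower triangle: Mantel r undefined")
  r_obs <- stats::cor(xa, mB[keep])
  n <- nrow(mA)
  has_na <- anyNA(mA) || anyNA(mB)
  ij <- which(lower.tri(mA), arr.ind = TRUE)   # fast path index pairs
  hits <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, "mantel"), {
    h <- 0L
    for (i in seq_len(n_perm)) {
      perm <- sample.int(n)
      if (has_na) {
        mBp <- mB[perm, perm]
        keep_p <- lt & !is.na(mA) & !is.na(mBp)
        r_p <- stats::cor(mA[keep_p], mBp[keep_p])
      } else {
        r_p <- stats::cor(xa, mB[cbind(perm[ij[, 1L]], perm[ij[, 2L]])])
      }
      extreme <- if (tail == "one_sided_positive") r_p >= r_obs - 1e-12
                 else abs(r_p) >= abs(r_obs) - 1e-12
      if (isTRUE(extreme)) h <- h + 1L
    }
    h
  })
  structure(list(r = r_obs, p = (1 + hits) / (n_perm + 1),
                 n_perm = as.integer(n_perm), tail = tail, seed = seed,
                 n_pairs = sum(keep)),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%s, %d permutations, %d pairs)\n",
              x$r, x$p, x$tail, x$n_perm, x$n_pairs))
  invisible(x)
}

#' Linearized isolation-by-distance regression
#'
#' Ordinary least squares of the linearized differentiation `x / (1 - x)`
#' on the natural log of geographic distance over all lower-triangle pairs:
#' `x/(1-x) = a + b ln(d)`. Significance comes from a Mantel permutation
#' test on the same transformed matrices. Any differentiation entry >= 1
#' makes the linearization infinite and is an error; zero-distance pairs
#' are excluded with their count reported.
#'
#' @param diff_matrix labeled symmetric differentiation matrix (entries
#'   < 1; e.g. pairwise G_ST or F_ST).
#' @param geo_matrix labeled symmetric geographic distance matrix
#'   (positive off-diagonal entries).
#' @param n_perm,seed passed to [mantel()].
#' @return object of class `ibd_regression`: list with `a` (intercept),
#'   `b` (slope), `r` (Pearson correlation), `p` (Mantel permutation p),
#'   `n_pairs`, `n_excluded`, `transform`.
#' @export
ibd_regression <- function(diff_matrix, geo_matrix, n_perm = 10000L,
                           seed = NULL) {
  check_dist_pair(diff_matrix, geo_matrix)
  off <- lower.tri(diff_matrix)
  if (any(diff_matrix[off] >= 1, na.rm = TRUE))
    stop("differentiation >= 1: linearization x/(1-x) is infinite")
  lin <- diff_matrix / (1 - diff_matrix)
  lnd <- suppressWarnings(log(geo_matrix))
  lnd[!is.finite(lnd)] <- NA_real_
  keep <- off & !is.na(lin) & !is.na(lnd)
  n_excluded <- sum(off & (is.na(lin) | is.na(lnd)))
  x <- lnd[keep]; y <- lin[keep]
  if (length(x) < 3L) stop("fewer than 3 usable pairs")
  fit <- stats::lm(y ~ x)
  r <- if (stats::sd(y) == 0) NA_real_ else stats::cor(x, y)
  p <- tryCatch(mantel(lin, lnd, n_perm = n_perm, seed = seed)$p,
                error = function(e) NA_real_)
  structure(list(a = unname(stats::coef(fit)[1L]),
                 b = unname(stats::coef(fit)[2L]),
                 r = r, p = p, n_pairs = length(x), n_excluded = n_excluded,
                 transform = "x/(1-x) ~ ln(distance)"),
            class = "ibd_regression")
}

#' @export
print.ibd_regression <- function(x, ...) {
  cat(sprintf("IBD regression %s: a = %.4f, b = %.4f, r = %s, p = %.4g (%d pairs",
              x$transform, x$a, x$b,
              ifelse(is.na(x$r), "NA", sprintf("%.4f", x$r)), x$p, x$n_pairs))
  if (x$n_excluded) cat(",", x$n_excluded, "excluded")
  cat(")\n")
  invisible(x)
}

#' Correlation between two distance matrices
#'
#' Pearson r over lower triangles, with a Mantel permutation p (default) or
#' the parametric Pearson p computed as if pairs were independent.
#'
#' @param mA,mB labeled symmetric matrices.
#' @param method `"mantel"` or `"parametric"`.
#' @param n_perm,seed,tail passed to [mantel()] when `method = "mantel"`.
#' @return list with `r`, `p`, `n_pairs`, `method`.
#' @export
correlate_matrices <- function(mA, mB, method = c("mantel", "parametric"),
                               n_perm = 10000L, seed = NULL,
                               tail = "two_sided") {
  method <- match.arg(method)
  if (method == "mantel") {
    mr <- mantel(mA, mB, n_perm = n_perm, seed = seed, tail = tail)
    return(list(r = mr$r, p = mr$p, n_pairs = mr$n_pairs, method = method))
  }
  check_dist_pair(mA, mB)
  keep <- lower.tri(mA) & !is.na(mA) & !is.na(mB)
  ct <- stats::cor.test(mA[keep], mB[keep])
  list(r = unname(ct$estimate), p = ct$p.value, n_pairs = sum(keep),
       method = method)
}

#' Correlation table between Q_ST matrices and predictor matrices
#'
#' One row per (trait-by-year Q_ST matrix, predictor matrix) combination
#' with Pearson r, p, the retained pair count (undefined Q_ST cells are
#' pairwise-deleted), and significance stars (`ns` / `*` / `**` / `***` at
#' 0.05 / 0.01 / 0.001). p-values are not adjusted for multiple testing by
#' default; `adjust = "holm"` applies a Holm correction across the table.
#'
#' @param qst_matrices named list of labeled symmetric Q_ST matrices.
#' @param predictor_matrices named list of predictor matrices (geography,
#'   climate variables, ...).
#' @param method,n_perm,seed passed to [correlate_matrices()].
#' @param adjust `"none"` (default) or `"holm"`.
#' @return data frame: `trait`, `predictor`, `r`, `p`, `n_pairs`, `signif`.
#' @export
qst_correlation_table <- function(qst_matrices, predictor_matrices,
                                  method = "mantel", n_perm = 999L,
                                  seed = NULL, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  stopifnot(length(qst_matrices) >= 1L, length(predictor_matrices) >= 1L)
  rows <- list()
  for (tr in names(qst_matrices)) for (pv in names(predictor_matrices)) {
    res <- correlate_matrices(qst_matrices[[tr]], predictor_matrices[[pv]],
                              method = method, n_perm = n_perm,
                              seed = if (is.null(seed)) NULL
                                     else derive_seed(seed, paste(tr, pv)))
    rows[[length(rows) + 1L]] <- data.frame(
      trait = tr, predictor = pv, r = res$r, p = res$p,
      n_pairs = res$n_pairs, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (adjust == "holm") out$p <- stats::p.adjust(out$p, method = "holm")
  out$signif <- p_stars(out$p)
  out
}
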