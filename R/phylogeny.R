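#' Neighbor-joining tree from a genetic distance matrix
#'
#' Saitou-Nei neighbor joining (via `ape::nj`) on a labeled symmetric
#' matrix. Negative branch lengths — an NJ artifact on non-additive
#' matrices — are clamped to zero with the deficit transferred to the
#' sister branch, so total path lengths are preserved as closely as the
#' clamp allows; the number of clamped edges is recorded in attribute
#' `n_clamped`. Infinite entries are an error: cap infinite genetic
#' distances explicitly before tree building.
#'
#' @param dm labeled symmetric matrix (>= 3 labels, finite entries).
#' @return an `ape::phylo` tree (unrooted).
#' @export
neighbor_joining <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) < 3L) stop("need >= 3 labels")
  if (any(!is.finite(dm)))
    stop("non-finite distances: cap infinite genetic distances before NJ")
  if (is.null(rownames(dm))) stop("matrix must carry labels")
  tr <- ape::nj(stats::as.dist(dm))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]
    parent <- tr$edge[e, 1L]
    sisters <- setdiff(which(tr$edge[, 1L] == parent), e)
    if (length(sisters)) {
      tr$edge.length[sisters[1L]] <- tr$edge.length[sisters[1L]] + deficit
    }
    tr$edge.length[e] <- 0
  }
  attr(tr, "n_clamped") <- length(neg)
  tr
}

#' Locus-bootstrap support for the NJ tree
#'
#' Builds the tree from the full-data Nei (1972) distance, then resamples
#' loci with replacement `n_boot` times, recomputes the distance and the NJ
#' tree per replicate, and scores each internal edge of the original tree
#' by the fraction of replicates containing the same bipartition. Supports
#' are stored in `tree$node.label` as fractions in [0, 1].
#'
#' @param gt a `genotype_table` with >= 2 loci.
#' @param n_boot bootstrap replicates (customary default 1000).
#' @param seed integer seed.
#' @param cap replacement value for infinite Nei distances (fixed allele
#'   differences); default twice the largest finite distance.
#' @return the original NJ tree with node labels set to supports and
#'   attribute `n_boot`.
#' @export
bootstrap_support <- function(gt, n_boot = 1000L, seed = 1L, cap = NULL) {
  af <- if (inherits(gt, "allele_freqs")) gt else allele_frequencies(gt)
  if (length(af$loci) < 2L) stop("locus bootstrap requires >= 2 loci")
  jt <- nei_identity_tables(af)
  cap_matrix <- function(m) {
    if (any(is.infinite(m))) {
      cc <- if (is.null(cap)) 2 * max(m[is.finite(m)]) else cap
      m[is.infinite(m)] <- cc
    }
    m
  }
  d0 <- cap_matrix(suppressWarnings(nei_distance_from_identity(jt)))
  tree <- neighbor_joining(d0)
  n_loci <- length(af$loci)
  reps <- with_seed(derive_seed(seed, "treeboot"), {
    lapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n_loci, n_loci, replace = TRUE)
      d <- cap_matrix(suppressWarnings(nei_distance_from_identity(jt, idx)))
      neighbor_joining(d)
    })
  })
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  tree$node.label <- formatC(counts / n_boot, format = "f", digits = 3)
  ## the basal node of an unrooted tree is not a bipartition; blank it
  tree$node.label[1L] <- ""
  attr(tree, "n_boot") <- as.integer(n_boot)
  tree
}

## Quote a Newick label when it contains metacharacters.
newick_label <- function(x) {
  if (grepl("[][ ():;,']", x)) {
    paste0("'", gsub("'", "''", x), "'")
  } else x
}

#' Write a tree as Newick text
#'
#' Standard Newick with branch lengths; internal node labels (e.g.
#' bootstrap supports) are written after the closing parenthesis. Labels
#' containing Newick metacharacters (spaces, parentheses, colons, ...) are
#' single-quoted per the standard. Output round-trips through
#' [read_newick()].
#'
#' @param tree an `ape::phylo` object.
#' @param path optional file path; when `NULL` the Newick string is
#'   returned.
#' @param digits significant digits for branch lengths.
#' @return the Newick string (invisibly when written to `path`).
#' @export
write_newick <- function(tree, path = NULL, digits = 10L) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  fmt <- function(x) sprintf("%.*g", digits, x)
  rec <- function(node, edge_len) {
    lab <- if (node <= n_tip) newick_label(tree$tip.label[node]) else {
      kids <- children[[as.character(node)]]
      inner <- vapply(kids, function(e)
        rec(tree$edge[e, 2L], tree$edge.length[e]), character(1L))
      nl <- if (!is.null(tree$node.label)) {
        l <- tree$node.label[node - n_tip]
        if (is.na(l) || l == "") "" else newick_label(l)
      } else ""
      paste0("(", paste(inner, collapse = ","), ")", nl)
    }
    if (is.na(edge_len)) lab else paste0(lab, ":", fmt(edge_len))
  }
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  txt <- paste0(rec(root, NA_real_), ";")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read Newick text
#'
#' Parses Newick (including single-quoted labels) into an `ape::phylo`
#' tree. Quoted labels are protected by placeholder substitution before the
#' `ape` parser runs, then restored.
#'
#' @param text a Newick string, or the path of a file holding one.
#' @return an `ape::phylo` object.
#' @export
read_newick <- function(text) {
  if (length(text) == 1L && !grepl(";", text) && file.exists(text))
    text <- paste(readLines(text), collapse = "")
  labels <- character(0)
  m <- gregexpr("'(?:[^']|'')*'", text)[[1L]]
  if (m[1L] != -1L) {
    pieces <- regmatches(text, gregexpr("'(?:[^']|'')*'", text))[[1L]]
    for (i in seq_along(pieces)) {
      ph <- sprintf("QLBL%03dX", i)
      labels[ph] <- gsub("''", "'", substr(pieces[i], 2L, nchar(pieces[i]) - 1L))
      text <- sub(pieces[i], ph, text, fixed = TRUE)
    }
  }
  tr <- ape::read.tree(text = text)
  restore <- function(x) {
    hit <- x %in% names(labels)
    x[hit] <- labels[x[hit]]
    x
  }
  tr$tip.label <- restore(tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- restore(tr$node.label)
  tr
}

#' Evanno delta-K from a clustering likelihood table
#'
#' Given replicate-run log-likelihoods `Ln P(D)` for consecutive K values,
#' computes the Evanno statistics: `L'(K) = mean L(K) - mean L(K-1)`,
#' `L''(K) = |L'(K+1) - L'(K)|`, and `delta K = L''(K) / SD(L(K))`. Delta-K
#' is defined only for interior K; K values whose runs have zero SD are
#' flagged (`delta_k = NA`).
#'
#' @param runs data frame with columns `K` and `lnP` (one row per run), or
#'   a matrix/list with K values as names/rows.
#' @return data frame of class `delta_k_table`: `K`, `n_runs`, `mean_lnP`,
#'   `sd_lnP`, `lprime`, `ldprime`, `delta_k`; attribute `best_k` is the
#'   argmax of `delta_k`.
#' @export
evanno_delta_k <- function(runs) {
  if (is.matrix(runs)) {
    runs <- data.frame(K = as.integer(rep(rownames(runs), ncol(runs))),
                       lnP = as.numeric(runs))
  }
  stopifnot(is.data.frame(runs), all(c("K", "lnP") %in% names(runs)))
  ks <- sort(unique(runs$K))
  if (length(ks) < 3L) stop("need >= 3 consecutive K values")
  if (any(diff(ks) != 1L)) stop("K values must be consecutive")
  n_runs <- tapply(runs$lnP, runs$K, length)[as.character(ks)]
  if (any(n_runs < 2L)) stop("need >= 2 runs per K")
  mu <- tapply(runs$lnP, runs$K, mean)[as.character(ks)]
  sdv <- tapply(runs$lnP, runs$K, stats::sd)[as.character(ks)]
  nK <- length(ks)
  lprime <- c(NA, diff(mu))
  ldprime <- rep(NA_real_, nK)
  ldprime[2:(nK - 1L)] <- abs(lprime[3:nK] - lprime[2:(nK - 1L)])
  delta_k <- ldprime / sdv
  flagged <- !is.na(ldprime) & sdv == 0
  delta_k[flagged] <- NA_real_
  out <- data.frame(K = ks, n_runs = as.integer(n_runs), mean_lnP = as.numeric(mu),
                    sd_lnP = as.numeric(sdv), lprime = as.numeric(lprime),
                    ldprime = ldprime, delta_k = as.numeric(delta_k))
  best <- if (all(is.na(out$delta_k))) NA_integer_
          else out$K[which.max(out$delta_k)]
  structure(out, best_k = best, n_flagged_sd0 = sum(flagged),
            class = c("delta_k_table", "data.frame"))
}
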