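#' Construct a genotype table
#'
#' A genotype table holds codominant diploid calls (e.g. SSR alleles) for a
#' set of individuals at a shared set of loci. Internally it is a data frame
#' with columns `individual`, `population`, then two integer allele columns
#' per locus named `<locus>_1` and `<locus>_2`. Allele codes are positive
#' integers; a missing genotype is encoded as the pair (0, 0) — a genotype is
#' either fully observed or fully missing at a locus.
#'
#' @param individual character vector of unique individual ids.
#' @param population character vector of population labels, same length.
#' @param alleles named list, one element per locus, each a 2-column integer
#'   matrix (one row per individual) of allele codes.
#' @return an object of class `genotype_table`.
#' @export
genotype_table <- function(individual, population, alleles) {
  individual <- as.character(individual)
  population <- as.character(population)
  if (anyDuplicated(individual))
    stop("duplicate individual ids: ",
         paste(unique(individual[duplicated(individual)]), collapse = ", "))
  if (length(population) != length(individual))
    stop("individual and population lengths differ")
  if (is.null(names(alleles)) || any(names(alleles) == ""))
    stop("alleles must be a named list (one element per locus)")
  df <- data.frame(individual = individual, population = population,
                   stringsAsFactors = FALSE)
  for (loc in names(alleles)) {
    a <- alleles[[loc]]
    if (!is.matrix(a) || ncol(a) != 2L || nrow(a) != length(individual))
      stop("locus ", loc, ": expected a 2-column matrix with one row per individual")
    a <- matrix(as.integer(a), ncol = 2L)
    if (any(is.na(a)) || any(a < 0L))
      stop("locus ", loc, ": allele codes must be non-negative integers (0 = missing)")
    half <- xor(a[, 1L] == 0L, a[, 2L] == 0L)
    if (any(half))
      stop("locus ", loc, ": half-missing genotype in row(s) ",
           paste(which(half), collapse = ", "))
    df[[paste0(loc, "_1")]] <- a[, 1L]
    df[[paste0(loc, "_2")]] <- a[, 2L]
  }
  structure(df, loci = names(alleles),
            class = c("genotype_table", "data.frame"))
}

#' Locus names of a genotype table
#' @param gt a `genotype_table`.
#' @return character vector of locus names, in file/construction order.
#' @export
gt_loci <- function(gt) attr(gt, "loci")

#' Population labels of a genotype table
#' @param gt a `genotype_table`.
#' @return character vector of unique population labels, in order of first
#'   appearance.
#' @export
gt_populations <- function(gt) unique(gt$population)

## Two-column allele matrix for one locus.
gt_alleles <- function(gt, locus) {
  cbind(gt[[paste0(locus, "_1")]], gt[[paste0(locus, "_2")]])
}

#' Subset a genotype table
#'
#' @param gt a `genotype_table`.
#' @param populations populations to keep (default all).
#' @param loci loci to keep (default all).
#' @return a `genotype_table`.
#' @export
gt_subset <- function(gt, populations = NULL, loci = NULL) {
  keep <- if (is.null(populations)) rep(TRUE, nrow(gt)) else gt$population %in% populations
  loci <- if (is.null(loci)) gt_loci(gt) else loci
  missing_loci <- setdiff(loci, gt_loci(gt))
  if (length(missing_loci))
    stop("unknown loci: ", paste(missing_loci, collapse = ", "))
  al <- lapply(loci, function(l) gt_alleles(gt, l)[keep, , drop = FALSE])
  names(al) <- loci
  genotype_table(gt$individual[keep], gt$population[keep], al)
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("Genotype table: ", nrow(x), " individuals, ",
      length(gt_populations(x)), " populations, ",
      length(gt_loci(x)), " loci\n", sep = "")
  invisible(x)
}

#' Read a genotype table from CSV
#'
#' Two dialects are supported.
#'
#' `"genalex"`: three header lines — line 1 gives `n_loci,n_individuals,
#' n_populations`; line 2 the per-population block sizes (`n_populations`
#' integers, in file order); line 3 the column header `individual,population`
#' followed by each locus name twice. Then one row per individual with two
#' allele columns per locus; missing allele = 0.
#'
#' `"long"`: a plain header `individual,population,locus,allele1,allele2`
#' and one row per individual x locus.
#'
#' @param path file path.
#' @param dialect `"genalex"` or `"long"`.
#' @return a `genotype_table` with loci ordered as in the file.
#' @export
read_genotypes <- function(path, dialect = c("genalex", "long")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "long") return(read_genotypes_long(path))
  lines <- readLines(path)
  if (length(lines) < 4L) stop("genalex file too short: ", path)
  counts <- as.integer(strsplit(lines[1L], ",")[[1L]])
  if (length(counts) < 3L || any(is.na(counts[1:3])))
    stop("genalex header line 1 must be n_loci,n_individuals,n_populations (row 1)")
  n_loci <- counts[1L]; n_ind <- counts[2L]; n_pop <- counts[3L]
  sizes <- as.integer(strsplit(lines[2L], ",")[[1L]])
  sizes <- sizes[!is.na(sizes)]
  if (length(sizes) != n_pop || sum(sizes) != n_ind)
    stop("genalex header line 2: expected ", n_pop,
         " population block sizes summing to ", n_ind, " (row 2)")
  header <- strsplit(lines[3L], ",")[[1L]]
  allele_cols <- header[-(1:2)]
  allele_cols <- allele_cols[allele_cols != ""]
  if (length(allele_cols) %% 2L != 0L)
    stop("odd number of allele columns in header (row 3)")
  loci <- allele_cols[seq(1L, length(allele_cols), by = 2L)]
  if (length(loci) != n_loci)
    stop("header declares ", n_loci, " loci but ", length(loci),
         " allele-column pairs found (row 3)")
  body <- utils::read.csv(textConnection(lines[-(1:3)]), header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(body) != 2L + 2L * n_loci)
    stop("data rows have ", ncol(body) - 2L, " allele columns; expected ", 2L * n_loci)
  if (nrow(body) != n_ind)
    stop("expected ", n_ind, " data rows, found ", nrow(body))
  al <- lapply(seq_len(n_loci), function(i) {
    as.matrix(body[, (2L * i + 1L):(2L * i + 2L)])
  })
  names(al) <- loci
  genotype_table(body[[1L]], body[[2L]], al)
}

read_genotypes_long <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual", "population", "locus", "allele1", "allele2")
  if (!all(need %in% names(df)))
    stop("long dialect requires columns: ", paste(need, collapse = ", "))
  loci <- unique(df$locus)
  inds <- unique(df$individual)
  pop_of <- df$population[match(inds, df$individual)]
  al <- lapply(loci, function(l) {
    sub <- df[df$locus == l, ]
    if (anyDuplicated(sub$individual))
      stop("locus ", l, ": duplicate rows for individual ",
           sub$individual[duplicated(sub$individual)][1L])
    m <- matrix(0L, nrow = length(inds), ncol = 2L)
    idx <- match(sub$individual, inds)
    m[idx, 1L] <- as.integer(sub$allele1)
    m[idx, 2L] <- as.integer(sub$allele2)
    m
  })
  names(al) <- loci
  genotype_table(inds, pop_of, al)
}

#' Write a genotype table to CSV
#'
#' @param gt a `genotype_table`.
#' @param path output path.
#' @param dialect `"genalex"` or `"long"` (see [read_genotypes()]).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gt, path, dialect = c("genalex", "long")) {
  dialect <- match.arg(dialect)
  loci <- gt_loci(gt)
  if (dialect == "long") {
    rows <- do.call(rbind, lapply(loci, function(l) {
      a <- gt_alleles(gt, l)
      data.frame(individual = gt$individual, population = gt$population,
                 locus = l, allele1 = a[, 1L], allele2 = a[, 2L],
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  ## order rows by population blocks (first-appearance order)
  pops <- gt_populations(gt)
  ord <- order(match(gt$population, pops))
  gt2 <- gt[ord, , drop = FALSE]
  sizes <- as.integer(table(factor(gt2$population, levels = pops)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(length(loci), nrow(gt2), length(pops), sep = ","), con)
  writeLines(paste(sizes, collapse = ","), con)
  writeLines(paste(c("individual", "population", rep(loci, each = 2L)),
                   collapse = ","), con)
  body <- cbind(gt2$individual, gt2$population,
                do.call(cbind, lapply(loci, function(l)
                  apply(gt_alleles(gt2, l), 2L, as.character))))
  writeLines(apply(body, 1L, paste, collapse = ","), con)
  invisible(path)
}

#' Per-population allele frequencies
#'
#' Computes, for every population x locus cell, the allele frequency vector
#' and the number of non-missing diploid individuals. Cells with zero typed
#' individuals are flagged undefined (frequency `NA`), never silently zero.
#'
#' @param gt a `genotype_table`.
#' @return an object of class `allele_freqs`: a list with elements
#'   \describe{
#'     \item{pops, loci}{label vectors}
#'     \item{freq}{`freq[[locus]]` is a populations x alleles matrix of
#'       frequencies (rows sum to 1, or all-`NA` when undefined)}
#'     \item{counts}{`counts[[locus]]`: populations x alleles allele counts}
#'     \item{het}{`het[[locus]]`: populations x alleles counts of
#'       heterozygous individuals carrying each allele}
#'     \item{n}{populations x loci matrix of typed diploid counts}
#'     \item{ho}{populations x loci matrix of observed heterozygote
#'       fractions}
#'   }
#' @export
allele_frequencies <- function(gt) {
  pops <- gt_populations(gt)
  loci <- gt_loci(gt)
  popf <- factor(gt$population, levels = pops)
  n <- matrix(0L, length(pops), length(loci), dimnames = list(pops, loci))
  ho <- matrix(NA_real_, length(pops), length(loci), dimnames = list(pops, loci))
  freq <- counts <- het <- stats::setNames(vector("list", length(loci)), loci)
  for (l in loci) {
    a <- gt_alleles(gt, l)
    ok <- a[, 1L] > 0L
    alleles <- sort(unique(c(a[ok, 1L], a[ok, 2L])))
    cnt <- matrix(0L, length(pops), length(alleles),
                  dimnames = list(pops, as.character(alleles)))
    hetm <- cnt
    for (k in 1:2) {
      tb <- table(popf[ok], factor(a[ok, k], levels = alleles))
      cnt <- cnt + unclass(tb)
    }
    is_het <- ok & a[, 1L] != a[, 2L]
    for (k in 1:2) {
      tb <- table(popf[is_het], factor(a[is_het, k], levels = alleles))
      hetm <- hetm + unclass(tb)
    }
    ## a heterozygote carrying allele x contributes once to het[, x] per copy;
    ## both its alleles differ, so each column counts individuals
    n[, l] <- as.integer(table(popf[ok]))
    ho[, l] <- as.numeric(table(popf[is_het])) / n[, l]
    ho[n[, l] == 0L, l] <- NA_real_
    fr <- cnt / (2 * n[, l])
    fr[n[, l] == 0L, ] <- NA_real_
    freq[[l]] <- fr
    counts[[l]] <- cnt
    het[[l]] <- hetm
  }
  structure(list(pops = pops, loci = loci, freq = freq, counts = counts,
                 het = het, n = n, ho = ho),
            class = "allele_freqs")
}

#' @export
print.allele_freqs <- function(x, ...) {
  cat("Allele frequencies: ", length(x$pops), " populations x ",
      length(x$loci), " loci\n", sep = "")
  undef <- sum(x$n == 0L)
  if (undef) cat("  undefined cells (no typed individuals):", undef, "\n")
  invisible(x)
}
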