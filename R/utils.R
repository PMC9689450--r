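#' @keywords internal
"_PACKAGE"

## Seed streams: one user-facing integer seed per stochastic entry point,
## sub-streams derived deterministically so independent stages never share
## a random stream.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((abs(seed) * 7919 + h * 104729 + 1) %% .Machine$integer.max)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Significance stars
#'
#' Maps p-values to the star notation used throughout the report tables:
#' `***` for p < 0.001, `**` for 0.001 <= p < 0.01, `*` for 0.01 <= p < 0.05,
#' `ns` otherwise.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param max_stars maximum number of stars the table convention allows
#'   (the neutrality-test table uses two).
#' @return character vector of the same length.
#' @export
p_stars <- function(p, max_stars = 3L) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  out <- ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "ns"))))
  if (max_stars < 3L) out[out == "***"] <- strrep("*", max_stars)
  out
}

## Lower-triangle extraction in a fixed, documented order (column-major,
## i > j), shared by every matrix-correlation routine.
lower_tri <- function(m) m[lower.tri(m)]

sd0 <- function(x) if (length(x) <= 1L) 0 else stats::sd(x)
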