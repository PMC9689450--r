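#' Parse degree-minute(-second) coordinate text
#'
#' Accepts `D°M′`, `D°M′S″`, with straight or typographic quote glyphs and
#' an optional hemisphere letter (N/S/E/W, prefix or suffix). Plain decimal
#' text is passed through.
#'
#' @param text character vector.
#' @return decimal degrees (signed: S and W negative).
#' @export
parse_dms <- function(text) {
  vapply(as.character(text), function(x) {
    raw <- trimws(x)
    if (grepl("^[-+]?[0-9.]+$", raw)) return(as.numeric(raw))
    hemi <- 1
    if (grepl("[SsWw]", raw)) hemi <- -1
    s <- gsub("[NnSsEeWw ]", "", raw)
    ## normalise glyphs: degree, minutes (' ′ ’), seconds (" ″)
    s <- gsub("°", ";", s)
    s <- gsub("[′’']", ";", s)
    s <- gsub("[″”\"]", ";", s)
    parts <- strsplit(s, ";")[[1L]]
    parts <- parts[parts != ""]
    if (length(parts) < 1L || length(parts) > 3L || anyNA(suppressWarnings(as.numeric(parts))))
      stop("malformed coordinate: ", x)
    num <- as.numeric(parts)
    if (length(num) >= 2L && num[2L] >= 60) stop("minutes >= 60 in: ", x)
    if (length(num) == 3L && num[3L] >= 60) stop("seconds >= 60 in: ", x)
    deg <- num[1L] + (if (length(num) >= 2L) num[2L] / 60 else 0) +
      (if (length(num) == 3L) num[3L] / 3600 else 0)
    hemi * deg
  }, numeric(1L), USE.NAMES = FALSE)
}

## Cartesian embedding of (lat, lon, elevation) on a sphere of radius R + h.
geo_xyz <- function(lat_deg, lon_deg, elev_m, R) {
  la <- lat_deg * pi / 180
  lo <- lon_deg * pi / 180
  r <- elev_m + R
  cbind(x = r * cos(la) * cos(lo),
        y = r * cos(la) * sin(lo),
        z = r * sin(la))
}

#' Chord distance between two sites
#'
#' Straight-line (through-Earth) Euclidean distance between two points
#' embedded on a sphere of radius `R` plus site elevation:
#' x = (h + R) cos(lat) cos(lon), y = (h + R) cos(lat) sin(lon),
#' z = (h + R) sin(lat). Elevation and `R` share units (meters).
#'
#' @param p1,p2 lists or one-row data frames with `latitude`, `longitude`
#'   (decimal degrees) and `elevation` (m).
#' @param R sphere radius in meters (> 0); default mean Earth radius.
#' @return distance in meters.
#' @export
chord_distance <- function(p1, p2, R = 6371000) {
  if (R <= 0) stop("R must be > 0")
  a <- geo_xyz(p1$latitude, p1$longitude, p1$elevation, R)
  b <- geo_xyz(p2$latitude, p2$longitude, p2$elevation, R)
  sqrt(sum((a - b)^2))
}

#' Read population metadata
#'
#' CSV with columns `population`, `latitude`, `longitude`, `elevation`.
#' Coordinates may be decimal degrees or degree-minute text (auto-detected
#' per cell via [parse_dms()]).
#'
#' @param path CSV path.
#' @return data frame with decimal-degree coordinates.
#' @export
read_population_meta <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("population", "latitude", "longitude", "elevation")
  if (!all(need %in% names(df)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  df$population <- as.character(df$population)
  df$latitude <- parse_dms(df$latitude)
  df$longitude <- parse_dms(df$longitude)
  df$elevation <- as.numeric(df$elevation)
  if (any(abs(df$latitude) > 90) || any(abs(df$longitude) > 180))
    stop("coordinates out of range")
  df
}

#' Pairwise chord-distance matrix (+ log companion)
#'
#' All pairwise chord distances between populations, with a companion
#' matrix of natural logarithms for isolation-by-distance regressions.
#' Coincident sites give distance 0; their log cells are `NA` (flagged for
#' exclusion downstream).
#'
#' @param meta data frame with `population`, `latitude`, `longitude`,
#'   `elevation` (decimal degrees / meters).
#' @param R sphere radius in meters.
#' @return list: `distance` (labeled symmetric matrix, meters),
#'   `log_distance` (natural log, `NA` on the diagonal and for coincident
#'   pairs), `n_zero_pairs`.
#' @export
geographic_distance_matrix <- function(meta, R = 6371000) {
  if (nrow(meta) < 2L) stop("need >= 2 populations")
  xyz <- geo_xyz(meta$latitude, meta$longitude, meta$elevation, R)
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), `+`) - 2 * xyz %*% t(xyz)
  d <- sqrt(pmax(d2, 0))
  dimnames(d) <- list(meta$population, meta$population)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  ld <- suppressWarnings(log(d))
  ld[!is.finite(ld)] <- NA_real_
  n_zero <- (sum(d == 0) - nrow(d)) / 2
  if (n_zero > 0)
    warning(n_zero, " coincident population pair(s): log distance set NA")
  list(distance = d, log_distance = ld, n_zero_pairs = n_zero)
}

#' Per-variable climate distance matrices
#'
#' For each climate variable, entry (i, j) is the absolute difference of
#' the population means. Missing cells are an error naming the population
#' and variable.
#'
#' @param ct data frame: `population` plus one numeric column per variable.
#' @return named list of labeled symmetric matrices, one per variable.
#' @export
climate_distance_matrices <- function(ct) {
  if (!"population" %in% names(ct)) stop("climate table needs a population column")
  vars <- setdiff(names(ct), "population")
  if (!length(vars)) stop("climate table has no variables")
  out <- lapply(vars, function(v) {
    x <- ct[[v]]
    if (anyNA(x))
      stop("missing climate value: population ",
           ct$population[which(is.na(x))[1L]], ", variable ", v)
    m <- abs(outer(x, x, `-`))
    dimnames(m) <- list(ct$population, ct$population)
    m
  })
  stats::setNames(out, vars)
}
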