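#' Simulate population coordinates and climate means
#'
#' Draws population sites uniformly in a latitude/longitude box with
#' non-negative elevations, then builds per-population climate variables as
#' linear functions of latitude plus Gaussian noise, so climate distance and
#' geographic distance are correlated by construction. The strength of that
#' correlation is set per variable by the ratio of `slope` to `noise_sd`
#' (slope 0 with positive noise gives geography-independent climate).
#'
#' @param n_pops number of populations (>= 2).
#' @param seed integer seed.
#' @param climate_spec named list, one element per climate variable, each a
#'   list with `slope` (units per degree latitude), `intercept`, and
#'   `noise_sd`; see [default_climate_spec()]. Must be non-empty.
#' @param lat_range,lon_range,elev_range sampling boxes (degrees, degrees,
#'   meters).
#' @return list: `meta` (data frame `population`, `latitude`, `longitude`,
#'   `elevation`) and `climate` (data frame `population` + one column per
#'   variable).
#' @export
simulate_geography_climate <- function(n_pops, seed = 1L,
                                       climate_spec = default_climate_spec(),
                                       lat_range = c(18, 39),
                                       lon_range = c(100, 120),
                                       elev_range = c(0, 1500)) {
  if (n_pops < 2L) stop("n_pops must be >= 2")
  if (!length(climate_spec)) stop("climate_spec must define at least one variable")
  if (is.null(names(climate_spec)) || any(names(climate_spec) == ""))
    stop("climate_spec must be a named list")
  with_seed(derive_seed(seed, "geoclimate"), {
    pops <- sprintf("pop%02d", seq_len(n_pops))
    lat <- stats::runif(n_pops, lat_range[1L], lat_range[2L])
    lon <- stats::runif(n_pops, lon_range[1L], lon_range[2L])
    elev <- stats::runif(n_pops, max(0, elev_range[1L]), elev_range[2L])
    meta <- data.frame(population = pops, latitude = lat, longitude = lon,
                       elevation = elev, stringsAsFactors = FALSE)
    climate <- data.frame(population = pops, stringsAsFactors = FALSE)
    for (v in names(climate_spec)) {
      s <- climate_spec[[v]]
      climate[[v]] <- s$intercept + s$slope * lat +
        stats::rnorm(n_pops, 0, s$noise_sd)
    }
    list(meta = meta, climate = climate)
  })
}

#' Default climate-variable specification
#'
#' Twenty-three variables shaped like a monthly-station climate summary:
#' temperature-type variables fall with latitude, pressure/humidity/wind
#' variables vary more weakly, all with station-level noise.
#'
#' @param n_vars number of variables (default 23).
#' @param slope,intercept,noise_sd defaults applied to every variable;
#'   slopes alternate in magnitude across variables to vary the
#'   geography-climate coupling.
#' @return named list usable as `climate_spec`.
#' @export
default_climate_spec <- function(n_vars = 23L, slope = -0.8, intercept = 25,
                                 noise_sd = 1) {
  vars <- sprintf("clim%02d", seq_len(n_vars))
  spec <- lapply(seq_len(n_vars), function(i) {
    list(slope = slope * (0.25 + 0.75 * (i %% 4) / 3),
         intercept = intercept, noise_sd = noise_sd)
  })
  stats::setNames(spec, vars)
}
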