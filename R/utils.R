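# Shared geometry and RNG helpers.

# Mean Earth radius, km. Equirectangular local distances are adequate at the
# < 100 km scales of along-shore spacing and capture zones.
EARTH_RADIUS_KM <- 6371

KM_PER_DEG_LAT <- EARTH_RADIUS_KM * pi / 180

#' Local equirectangular distance in kilometres
#'
#' Distance between points in decimal degrees, using a flat-Earth
#' (equirectangular) approximation scaled by `cos(latitude)` in longitude.
#' Accurate to well under 1% at the sub-100-km scales used for along-shore
#' spacing and larval capture zones.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorised).
#' @return distance in km.
#' @keywords internal
dist_km <- function(lat1, lon1, lat2, lon2) {
  midlat <- (lat1 + lat2) / 2
  dy <- (lat2 - lat1) * KM_PER_DEG_LAT
  dx <- (lon2 - lon1) * KM_PER_DEG_LAT * cos(midlat * pi / 180)
  sqrt(dx^2 + dy^2)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# min(1, m * p), the Bonferroni adjustment.

#' Bonferroni correction for multiple tests
#'
#' @param p numeric vector of raw p-values.
#' @param m number of tests in the family; must be at least `length(p)`.
#' @return adjusted p-values, `pmin(1, m * p)`.
#' @examples
#' bonferroni(c(0.01, 0.5), m = 10)
#' @export
bonferroni <- function(p, m = length(p)) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1, na.rm = TRUE))
  if (m < length(p)) stop("'m' must be at least the number of tests")
  pmin(1, m * p)
}

# stop() with a consistent prefix for user input errors
fail <- function(...) stop(..., call. = FALSE)
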