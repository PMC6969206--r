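# Synthetic coastal domains and daily surface-current series.
#
# These stand in for a data-assimilative ocean product: the aim is the
# statistical structure a drift simulation needs (a steady alongshore jet,
# mesoscale eddies, day-to-day noise, optional offshore-divergence zones
# that act as dispersal barriers), not hydrodynamic realism.

#' Flow recipe for synthetic velocity fields
#'
#' A named, versioned parameter set describing how daily surface currents are
#' composed: a steady alongshore jet, a travelling eddy field derived from a
#' periodic streamfunction, seeded Gaussian day-to-day noise, and optional
#' offshore-divergence "barrier" zones where the alongshore jet is suppressed
#' and flow is pushed offshore.
#'
#' @param mean_speed steady alongshore (eastward) jet speed, m/s.
#' @param eddy_amp eddy velocity amplitude, m/s (0 disables eddies).
#' @param eddy_wavelength_km eddy wavelength, km.
#' @param eddy_period_days eddy phase-propagation period, days.
#' @param noise_sd standard deviation of per-cell per-day velocity noise, m/s.
#' @param barriers longitudes (decimal degrees) of offshore-divergence zones.
#' @param barrier_width_km Gaussian e-folding half-width of each zone, km.
#' @param barrier_speed peak offshore speed inside a zone, m/s.
#' @param onshore_speed weak uniform cross-shore drift toward the coast,
#'   m/s (coastal convergence; keeps passive particles near the shore).
#' @param offshore_sign +1 if offshore is increasing latitude (land to the
#'   south), -1 otherwise.
#' @param name recipe label, recorded in outputs for provenance.
#' @return an object of class `flow_recipe`.
#' @examples
#' flow_recipe(mean_speed = 0.2, eddy_amp = 0)
#' @export
flow_recipe <- function(mean_speed = 0.2, eddy_amp = 0.05,
                        eddy_wavelength_km = 30, eddy_period_days = 10,
                        noise_sd = 0.02, barriers = numeric(0),
                        barrier_width_km = 5, barrier_speed = 0.3,
                        onshore_speed = 0, offshore_sign = 1,
                        name = "default-v1") {
  stopifnot(eddy_wavelength_km > 0, eddy_period_days > 0,
            barrier_width_km > 0, noise_sd >= 0, eddy_amp >= 0,
            offshore_sign %in% c(-1, 1))
  structure(list(mean_speed = mean_speed, eddy_amp = eddy_amp,
                 eddy_wavelength_km = eddy_wavelength_km,
                 eddy_period_days = eddy_period_days, noise_sd = noise_sd,
                 barriers = barriers, barrier_width_km = barrier_width_km,
                 barrier_speed = barrier_speed, onshore_speed = onshore_speed,
                 offshore_sign = offshore_sign, name = name),
            class = "flow_recipe")
}

# Close a polygon matrix (2 cols: lon, lat), dropping a duplicated last vertex.
normalize_polygon <- function(polygon) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2 || nrow(polygon) < 3) {
    fail("polygon must be a matrix with >= 3 rows and columns (lon, lat)")
  }
  storage.mode(polygon) <- "double"
  n <- nrow(polygon)
  if (all(polygon[1, ] == polygon[n, ])) polygon <- polygon[-n, , drop = FALSE]
  if (nrow(polygon) < 3) fail("polygon must have >= 3 distinct vertices")
  polygon
}

# TRUE if any two non-adjacent edges of the closed polygon properly intersect.
polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1), , drop = FALSE]
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent around the ring
      if (seg_int(a[i, ], b[i, ], a[j, ], b[j, ])) return(TRUE)
    }
  }
  FALSE
}

point_in_polygon <- function(lon, lat, poly) {
  mgcv::in.out(rbind(poly, poly[1, ]), cbind(lon, lat))
}

# Resample a polyline (matrix lon/lat) by arc length (km). `closed` loops
# back to the first vertex and excludes the duplicate endpoint.
resample_polyline_km <- function(line, spacing_km, closed) {
  if (closed) line <- rbind(line, line[1, ])
  n <- nrow(line)
  seg <- dist_km(line[-n, 2], line[-n, 1], line[-1, 2], line[-1, 1])
  cum <- c(0, cumsum(seg))
  total <- cum[n]
  if (spacing_km > total) fail("point spacing exceeds coastline length")
  s <- if (closed) {
    seq(0, total - 1e-9, by = spacing_km)
  } else {
    seq(0, total, by = spacing_km)
  }
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx[idx >= n] <- n - 1
  frac <- (s - cum[idx]) / pmax(seg[idx], 1e-12)
  cbind(lon = line[idx, 1] + frac * (line[idx + 1, 1] - line[idx, 1]),
        lat = line[idx, 2] + frac * (line[idx + 1, 2] - line[idx, 2]),
        along_km = s)
}

#' Build a coastal domain with regularly spaced source/sink points
#'
#' Rasterises a land polygon onto a regular latitude/longitude grid and places
#' source/sink ("coastal") points along the seaward boundary by arc-length
#' resampling, nudging each point just offshore so releases start in water.
#'
#' @param polygon land polygon: matrix with columns (lon, lat) in decimal
#'   degrees; may be open or closed.
#' @param grid_spacing_deg grid spacing in degrees (default 0.08, the
#'   resolution of typical eddy-resolving ocean products).
#' @param point_spacing_km along-shore spacing of coastal points, km
#'   (default 1).
#' @param coast_edges indices of polygon edges (edge `i` joins vertex `i` to
#'   `i + 1`) that form the coastline; `NULL` means the whole ring is coast.
#'   The seaward side is found automatically by testing which normal
#'   direction leaves the polygon.
#' @param bbox_margin_deg margin added around the polygon bounding box when
#'   building the grid.
#' @param nudge_km offshore displacement applied to each coastal point.
#' @return a `coastal_domain` with the grid, land mask (TRUE = land) and a
#'   data frame of coastal points (`id`, `lon`, `lat`, `along_km`).
#' @examples
#' sq <- square_island_polygon(side_km = 10)
#' dom <- build_coastal_domain(sq, grid_spacing_deg = 0.02,
#'                             point_spacing_km = 1)
#' nrow(dom$coastal_points)  # 40: perimeter 40 km at 1 km spacing
#' @export
build_coastal_domain <- function(polygon, grid_spacing_deg = 0.08,
                                 point_spacing_km = 1, coast_edges = NULL,
                                 bbox_margin_deg = 0.3, nudge_km = 0.25) {
  if (grid_spacing_deg <= 0) fail("grid_spacing_deg must be > 0")
  if (point_spacing_km <= 0) fail("point_spacing_km must be > 0")
  poly <- normalize_polygon(polygon)
  if (polygon_self_intersects(poly)) fail("polygon is self-intersecting")
  n <- nrow(poly)

  if (is.null(coast_edges)) {
    pts <- resample_polyline_km(poly, point_spacing_km, closed = TRUE)
  } else {
    coast_edges <- sort(unique(as.integer(coast_edges)))
    if (any(coast_edges < 1 | coast_edges > n)) fail("invalid coast_edges")
    verts <- poly[c(coast_edges, coast_edges[length(coast_edges)] %% n + 1), ,
                  drop = FALSE]
    pts <- resample_polyline_km(verts, point_spacing_km, closed = FALSE)
  }

  # grid over the polygon bbox plus margin
  lon <- seq(min(poly[, 1]) - bbox_margin_deg,
             max(poly[, 1]) + bbox_margin_deg, by = grid_spacing_deg)
  lat <- seq(min(poly[, 2]) - bbox_margin_deg,
             max(poly[, 2]) + bbox_margin_deg, by = grid_spacing_deg)
  cells <- expand.grid(lon = lon, lat = lat)
  land <- matrix(point_in_polygon(cells$lon, cells$lat, poly),
                 nrow = length(lat), ncol = length(lon), byrow = TRUE)

  # nudge each coastal point offshore along the local normal; the water side
  # is whichever normal direction exits the polygon
  np <- nrow(pts)
  nxt <- pmin(np, seq_len(np) + 1)
  prv <- pmax(1, seq_len(np) - 1)
  coslat <- cos(pts[, "lat"] * pi / 180)
  tx <- (pts[nxt, "lon"] - pts[prv, "lon"]) * coslat
  ty <- pts[nxt, "lat"] - pts[prv, "lat"]
  tl <- sqrt(tx^2 + ty^2)
  tl[tl == 0] <- 1
  nx <- -ty / tl
  ny <- tx / tl
  out <- matrix(NA_real_, np, 2)
  eps0 <- nudge_km / KM_PER_DEG_LAT
  for (mult in c(1, 2, 4)) {
    todo <- is.na(out[, 1])
    if (!any(todo)) break
    for (sgn in c(1, -1)) {
      cand_lon <- pts[, "lon"] + sgn * mult * eps0 * nx / coslat
      cand_lat <- pts[, "lat"] + sgn * mult * eps0 * ny
      ok <- todo & !point_in_polygon(cand_lon, cand_lat, poly) &
        cand_lon >= lon[1] & cand_lon <= lon[length(lon)] &
        cand_lat >= lat[1] & cand_lat <= lat[length(lat)]
      out[ok, 1] <- cand_lon[ok]
      out[ok, 2] <- cand_lat[ok]
      todo <- is.na(out[, 1])
    }
  }
  if (anyNA(out[, 1])) {
    bad <- is.na(out[, 1])
    out[bad, 1] <- pts[bad, "lon"]
    out[bad, 2] <- pts[bad, "lat"]
    warning(sum(bad), " coastal point(s) could not be nudged into water")
  }

  cp <- data.frame(id = seq_len(np), lon = out[, 1], lat = out[, 2],
                   boundary_lon = pts[, "lon"], boundary_lat = pts[, "lat"],
                   along_km = pts[, "along_km"])
  structure(list(land_polygon = poly, lon = lon, lat = lat,
                 grid_spacing_deg = grid_spacing_deg, land_mask = land,
                 coastal_points = cp, point_spacing_km = point_spacing_km),
            class = "coastal_domain")
}

#' Convenience polygon: square island of a given side length
#'
#' @param side_km side length in km.
#' @param center_lon,center_lat island centre, decimal degrees.
#' @return closed polygon matrix (lon, lat).
#' @export
square_island_polygon <- function(side_km = 10, center_lon = 20,
                                  center_lat = -34) {
  half_lat <- side_km / 2 / KM_PER_DEG_LAT
  half_lon <- side_km / 2 / (KM_PER_DEG_LAT * cos(center_lat * pi / 180))
  cbind(lon = center_lon + c(-1, 1, 1, -1) * half_lon,
        lat = center_lat + c(-1, -1, 1, 1) * half_lat)
}

#' Convenience polygon: east-west coastline with land to the south
#'
#' Builds a rectangular landmass whose northern edge is a straight coast of
#' the requested length. Edge 3 of the polygon (the northern edge) is the
#' coastline, so pass `coast_edges = 3` to [build_coastal_domain()].
#'
#' @param length_km coast length in km.
#' @param lat0 latitude of the coastline.
#' @param lon0 western end of the coastline.
#' @param land_depth_km north-south extent of the land block.
#' @return closed polygon matrix (lon, lat).
#' @export
straight_coast_polygon <- function(length_km = 60, lat0 = -34, lon0 = 20,
                                   land_depth_km = 20) {
  dlat <- land_depth_km / KM_PER_DEG_LAT
  dlon <- length_km / (KM_PER_DEG_LAT * cos(lat0 * pi / 180))
  # vertices counter-clockwise; edge 3 (NE -> NW) is the coast
  cbind(lon = c(lon0, lon0 + dlon, lon0 + dlon, lon0),
        lat = c(lat0 - dlat, lat0 - dlat, lat0, lat0))
}

#' Generate a daily velocity-field series from a flow recipe
#'
#' Composes, for every day, the recipe's steady alongshore jet, a travelling
#' eddy field (derived from a periodic streamfunction so it is divergence
#' free), seeded Gaussian noise and any offshore-divergence barrier zones.
#' Velocities are set to zero on land cells. The same (domain, recipe, seed)
#' always yields bit-identical arrays.
#'
#' @param domain a [coastal_domain][build_coastal_domain].
#' @param recipe a [flow_recipe()].
#' @param years number of simulated years.
#' @param days_per_year days per simulated year (default 365).
#' @param seed integer seed for the noise component.
#' @return a `velocity_fields` object: arrays `u`, `v` of dimension
#'   (lat, lon, time) in m/s, plus `times` (day index), `year` (year index
#'   per day), grid vectors, the recipe and the seed.
#' @export
generate_fields <- function(domain, recipe = flow_recipe(), years = 1,
                            days_per_year = 365, seed = 1) {
  stopifnot(inherits(domain, "coastal_domain"), inherits(recipe, "flow_recipe"))
  if (years < 1) fail("years must be >= 1")
  nlat <- length(domain$lat)
  nlon <- length(domain$lon)
  ndays <- years * days_per_year
  lat0 <- domain$lat[1]
  lon0 <- domain$lon[1]
  midlat <- mean(domain$lat)
  x_km <- (domain$lon - lon0) * KM_PER_DEG_LAT * cos(midlat * pi / 180)
  y_km <- (domain$lat - lat0) * KM_PER_DEG_LAT
  X <- matrix(x_km, nlat, nlon, byrow = TRUE)
  Y <- matrix(y_km, nlat, nlon)

  barrier_g <- matrix(0, nlat, nlon)
  if (length(recipe$barriers)) {
    xb <- (recipe$barriers - lon0) * KM_PER_DEG_LAT * cos(midlat * pi / 180)
    for (b in xb) {
      barrier_g <- pmax(barrier_g,
                        exp(-((X - b) / recipe$barrier_width_km)^2))
    }
  }

  u <- array(0, c(nlat, nlon, ndays))
  v <- array(0, c(nlat, nlon, ndays))
  lam <- recipe$eddy_wavelength_km
  with_seed(seed, {
    for (t in seq_len(ndays)) {
      phase <- 2 * pi * (t - 1) / recipe$eddy_period_days
      ut <- matrix(recipe$mean_speed, nlat, nlon) * (1 - barrier_g)
      vt <- recipe$offshore_sign *
        (recipe$barrier_speed * barrier_g -
           recipe$onshore_speed * (1 - barrier_g))
      if (recipe$eddy_amp > 0) {
        ut <- ut + recipe$eddy_amp *
          sin(2 * pi * X / lam - phase) * cos(2 * pi * Y / lam)
        vt <- vt - recipe$eddy_amp *
          cos(2 * pi * X / lam - phase) * sin(2 * pi * Y / lam)
      }
      if (recipe$noise_sd > 0) {
        ut <- ut + matrix(stats::rnorm(nlat * nlon, 0, recipe$noise_sd),
                          nlat, nlon)
        vt <- vt + matrix(stats::rnorm(nlat * nlon, 0, recipe$noise_sd),
                          nlat, nlon)
      }
      ut[domain$land_mask] <- 0
      vt[domain$land_mask] <- 0
      u[, , t] <- ut
      v[, , t] <- vt
    }
  })
  structure(list(times = seq_len(ndays),
                 year = rep(seq_len(years), each = days_per_year),
                 lat = domain$lat, lon = domain$lon, u = u, v = v,
                 seed = seed, recipe = recipe,
                 days_per_year = days_per_year),
            class = "velocity_fields")
}

#' @export
print.coastal_domain <- function(x, ...) {
  cat("Coastal domain\n")
  cat(sprintf("  grid: %d x %d cells at %.3f deg (%.0f%% land)\n",
              length(x$lat), length(x$lon), x$grid_spacing_deg,
              100 * mean(x$land_mask)))
  cat(sprintf("  coastal points: %d at %.2f km spacing\n",
              nrow(x$coastal_points), x$point_spacing_km))
  invisible(x)
}

#' @export
print.velocity_fields <- function(x, ...) {
  sp <- sqrt(x$u^2 + x$v^2)
  cat("Velocity field series\n")
  cat(sprintf("  %d days over %d year(s), %d x %d grid, seed %d\n",
              length(x$times), max(x$year), length(x$lat), length(x$lon),
              x$seed))
  cat(sprintf("  recipe '%s'; max speed %.3f m/s\n", x$recipe$name, max(sp)))
  invisible(x)
}

#' @export
plot.coastal_domain <- function(x, ...) {
  graphics::image(x$lon, x$lat, t(x$land_mask), col = c("lightblue", "tan"),
                  xlab = "Longitude", ylab = "Latitude", ...)
  graphics::points(x$coastal_points$lon, x$coastal_points$lat, pch = 16,
                   cex = 0.4)
  invisible(x)
}
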