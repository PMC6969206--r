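# Passive larval drift: daily releases from every coastal point, hourly
# forward-Euler advection with bilinear interpolation of the daily velocity
# field, settlement on contact with a coastal point's capture zone or with
# the shore, loss after the maximum pelagic duration or on leaving the
# domain.

#' Bilinearly interpolate a velocity field at particle positions
#'
#' Spatial interpolation uses the four grid nodes enclosing each position;
#' temporal interpolation is piecewise constant within a day (daily fields,
#' hourly queries), with optional linear blending between consecutive days.
#'
#' @param fields a [velocity_fields][generate_fields] object.
#' @param lon,lat query positions, decimal degrees (vectorised).
#' @param time_days continuous time in days since the series start (0 = start
#'   of day 1); determines which daily field is used.
#' @param time_blend if TRUE, blend linearly between the two bracketing
#'   daily fields instead of holding each day's field constant.
#' @return list with numeric vectors `u`, `v` (m/s); `NA` marks positions
#'   outside the grid ("out of domain").
#' @export
interpolate_velocity <- function(fields, lon, lat, time_days,
                                 time_blend = FALSE) {
  stopifnot(inherits(fields, "velocity_fields"))
  nlat <- length(fields$lat)
  nlon <- length(fields$lon)
  ntime <- length(fields$times)
  dlat <- fields$lat[2] - fields$lat[1]
  dlon <- fields$lon[2] - fields$lon[1]
  gi <- (lat - fields$lat[1]) / dlat
  gj <- (lon - fields$lon[1]) / dlon
  inside <- gi >= 0 & gi <= nlat - 1 & gj >= 0 & gj <= nlon - 1 &
    is.finite(gi) & is.finite(gj)
  i0 <- pmin(floor(gi), nlat - 2)
  j0 <- pmin(floor(gj), nlon - 2)
  i0[!inside] <- 0
  j0[!inside] <- 0
  wi <- gi - i0
  wj <- gj - j0

  day <- pmin(pmax(floor(time_days) + 1, 1), ntime)
  # index into the 3-D array by linear offsets (fast, no apply)
  pick <- function(A, ii, jj, dd) {
    A[ii + (jj - 1L) * nlat + (dd - 1L) * nlat * nlon]
  }
  interp_day <- function(A, dd) {
    i1 <- as.integer(i0) + 1L
    j1 <- as.integer(j0) + 1L
    a00 <- pick(A, i1, j1, dd)
    a01 <- pick(A, i1, j1 + 1L, dd)
    a10 <- pick(A, i1 + 1L, j1, dd)
    a11 <- pick(A, i1 + 1L, j1 + 1L, dd)
    (1 - wi) * ((1 - wj) * a00 + wj * a01) + wi * ((1 - wj) * a10 + wj * a11)
  }
  dd <- as.integer(day)
  u <- interp_day(fields$u, dd)
  v <- interp_day(fields$v, dd)
  if (time_blend) {
    d2 <- pmin(dd + 1L, ntime)
    w <- time_days - floor(time_days)
    u <- (1 - w) * u + w * interp_day(fields$u, d2)
    v <- (1 - w) * v + w * interp_day(fields$v, d2)
  }
  u[!inside] <- NA_real_
  v[!inside] <- NA_real_
  list(u = u, v = v)
}

#' Advance particle positions by one forward-Euler step
#'
#' Displacement is velocity times the step length, converted from metres to
#' degrees at each particle's current latitude.
#'
#' @param lon,lat current positions, decimal degrees.
#' @param u,v velocities, m/s.
#' @param dt_hours step length in hours (default 1).
#' @return list with `lon`, `lat` of the next positions.
#' @export
advect <- function(lon, lat, u, v, dt_hours = 1) {
  if (dt_hours <= 0) fail("dt_hours must be > 0")
  dt_s <- dt_hours * 3600
  m_per_deg <- KM_PER_DEG_LAT * 1000
  list(lon = lon + u * dt_s / (m_per_deg * cos(lat * pi / 180)),
       lat = lat + v * dt_s / m_per_deg)
}

#' Release and track passive larvae
#'
#' Releases `particles_per_point` particles from every coastal point on each
#' release day and advects them hourly until they settle in the capture zone
#' of a coastal point, beach on a land cell (settling at the nearest coastal
#' point), leave the domain, or exceed the pelagic larval duration.
#'
#' @param domain a [coastal_domain][build_coastal_domain].
#' @param fields a [velocity_fields][generate_fields] covering the schedule.
#' @param release_days integer day indices of the field series on which
#'   particles are released; defaults to every day that leaves a full
#'   `pld_days` of fields downstream.
#' @param particles_per_point particles released per coastal point per day.
#' @param pld_days maximum pelagic larval duration, days (default 30).
#' @param capture_radius_km settlement capture-zone radius around each
#'   coastal point, km (default 2).
#' @param precompetency_days minimum drift time before a particle is
#'   competent to settle (default 0).
#' @param diffusion_kmday standard deviation of an optional per-hour random
#'   walk, expressed in km per sqrt(day); 0 (default) keeps advection fully
#'   deterministic.
#' @param time_blend passed to [interpolate_velocity()].
#' @param store_tracks if TRUE, keep the hourly track of every particle.
#' @param seed RNG seed, used only when `diffusion_kmday > 0`.
#' @param year label attached to the result (e.g. the simulated year).
#' @return a `trajectory_set`: data frame `particles` with origin, release
#'   day, fate (`"settled"` or `"lost"`), settlement point, drift duration
#'   (days) and cumulative track distance (km); `released` counts per origin.
#' @export
run_release <- function(domain, fields, release_days = NULL,
                        particles_per_point = 1, pld_days = 30,
                        capture_radius_km = 2, precompetency_days = 0,
                        diffusion_kmday = 0, time_blend = FALSE,
                        store_tracks = FALSE, seed = NULL, year = 1L) {
  stopifnot(inherits(domain, "coastal_domain"),
            inherits(fields, "velocity_fields"))
  ntime <- length(fields$times)
  if (is.null(release_days)) {
    release_days <- seq_len(max(1, ntime - pld_days))
  }
  release_days <- as.integer(release_days)
  if (!length(release_days)) fail("empty release schedule")
  if (any(release_days < 1 | release_days > ntime)) {
    fail("release schedule outside the field's time span")
  }
  cp <- domain$coastal_points
  npt <- nrow(cp)
  n <- npt * length(release_days) * particles_per_point

  origin <- rep(rep(cp$id, each = particles_per_point),
                times = length(release_days))
  relday <- rep(release_days, each = npt * particles_per_point)
  lon <- cp$lon[origin]
  lat <- cp$lat[origin]
  fate <- integer(n)            # 0 active, 1 settled, 2 lost
  settle_id <- rep(NA_integer_, n)
  dist_km_cum <- numeric(n)
  end_age_h <- rep(NA_real_, n)

  tracks <- if (store_tracks) {
    lapply(seq_len(n), function(i) list(c(lon[i], lat[i])))
  } else NULL

  # shore contact is tested against the exact land polygon (the grid's land
  # mask only zeroes velocities), so tracks never end up strictly inland
  land_at <- function(plon, plat) {
    point_in_polygon(plon, plat, domain$land_polygon)
  }
  nearest_cp <- function(plon, plat) {
    # nearest coastal point id and distance (km) for each position
    d2 <- outer(plat, cp$lat, function(a, b) (a - b) * KM_PER_DEG_LAT)^2 +
      (outer(plon, cp$lon, "-") *
         (KM_PER_DEG_LAT * cos(plat * pi / 180)))^2
    j <- max.col(-d2, ties.method = "first")
    list(id = cp$id[j], dist = sqrt(d2[cbind(seq_along(plon), j)]))
  }

  max_h <- pld_days * 24
  h0 <- (min(release_days) - 1L) * 24L
  h1 <- (max(release_days) - 1L) * 24L + max_h
  sim <- function() {
    for (h in h0:(h1 - 1L)) {
      age <- h - (relday - 1L) * 24L
      act <- fate == 0L & age >= 0L & age < max_h
      if (!any(act)) {
        if (all(fate != 0L) && h > (max(release_days) - 1L) * 24L) break
        next
      }
      t_days <- h / 24
      if (t_days >= ntime) {            # ran out of fields: lost
        fate[act] <<- 2L
        end_age_h[act] <<- age[act]
        next
      }
      vel <- interpolate_velocity(fields, lon[act], lat[act], t_days,
                                  time_blend = time_blend)
      oob <- is.na(vel$u)
      if (any(oob)) {
        ids <- which(act)[oob]
        fate[ids] <<- 2L
        end_age_h[ids] <<- age[ids]
        act[ids] <- FALSE
        vel$u <- vel$u[!oob]
        vel$v <- vel$v[!oob]
      }
      if (!any(act)) next
      act_idx <- which(act)
      stepped <- act
      old_lon <- lon[act]
      old_lat <- lat[act]
      nxt <- advect(old_lon, old_lat, vel$u, vel$v, dt_hours = 1)
      if (diffusion_kmday > 0) {
        sd_deg <- diffusion_kmday * sqrt(1 / 24) / KM_PER_DEG_LAT
        nxt$lat <- nxt$lat + stats::rnorm(sum(act), 0, sd_deg)
        nxt$lon <- nxt$lon + stats::rnorm(sum(act), 0, sd_deg) /
          cos(old_lat * pi / 180)
      }
      lon[act] <<- nxt$lon
      lat[act] <<- nxt$lat
      dist_km_cum[act] <<- dist_km_cum[act] +
        dist_km(old_lat, old_lon, nxt$lat, nxt$lon)
      age1 <- age + 1L

      # shore contact: settles at the nearest coastal point once competent;
      # before competency the step is reverted (no drift across the coast)
      beach <- act
      beach[act] <- land_at(lon[act], lat[act])
      if (any(beach)) {
        competent <- age1 >= precompetency_days * 24
        bs <- beach & competent
        if (any(bs)) {
          nc <- nearest_cp(lon[bs], lat[bs])
          fate[bs] <<- 1L
          settle_id[bs] <<- nc$id
          end_age_h[bs] <<- age1[bs]
          # the track ends at the settlement point, not inland
          lon[bs] <<- cp$lon[match(nc$id, cp$id)]
          lat[bs] <<- cp$lat[match(nc$id, cp$id)]
          act <- act & !bs
        }
        br <- which(beach & !competent)
        if (length(br)) {
          # cancel the offending step, then slide along the shore: retry
          # with the alongshore component only, else stay put this hour
          pos <- match(br, act_idx)
          step_d <- dist_km(old_lat[pos], old_lon[pos], lat[br], lon[br])
          dist_km_cum[br] <<- dist_km_cum[br] - step_d
          slide <- advect(old_lon[pos], old_lat[pos], vel$u[pos], 0,
                          dt_hours = 1)
          ok <- !land_at(slide$lon, slide$lat)
          lon[br] <<- ifelse(ok, slide$lon, old_lon[pos])
          lat[br] <<- ifelse(ok, slide$lat, old_lat[pos])
          dist_km_cum[br[ok]] <<- dist_km_cum[br[ok]] +
            dist_km(old_lat[pos[ok]], old_lon[pos[ok]],
                    slide$lat[ok], slide$lon[ok])
        }
      }
      # capture-zone settlement once competent
      comp <- act & age1 >= precompetency_days * 24
      if (any(comp)) {
        nc <- nearest_cp(lon[comp], lat[comp])
        settle <- nc$dist <= capture_radius_km
        if (any(settle)) {
          ids <- which(comp)[settle]
          fate[ids] <<- 1L
          settle_id[ids] <<- nc$id[settle]
          end_age_h[ids] <<- age1[ids]
          act[ids] <- FALSE
        }
      }
      # pelagic duration exceeded
      expi <- act & age1 >= max_h
      if (any(expi)) {
        fate[expi] <<- 2L
        end_age_h[expi] <<- age1[expi]
      }
      if (store_tracks) {
        for (i in which(stepped)) {
          tracks[[i]][[length(tracks[[i]]) + 1L]] <<- c(lon[i], lat[i])
        }
      }
    }
  }
  if (diffusion_kmday > 0) with_seed(seed, sim()) else sim()
  fate[fate == 0L] <- 2L                      # safety: anything left is lost
  end_age_h[is.na(end_age_h)] <- max_h

  particles <- data.frame(
    particle_id = seq_len(n), origin_id = origin, release_day = relday,
    fate = c("settled", "lost")[fate], settle_id = settle_id,
    drift_days = end_age_h / 24, drift_km = dist_km_cum)
  released <- as.integer(table(factor(origin, levels = cp$id)))
  out <- structure(list(particles = particles,
                        released = stats::setNames(released, cp$id),
                        point_ids = cp$id, year = year,
                        capture_radius_km = capture_radius_km,
                        pld_days = pld_days),
                   class = "trajectory_set")
  if (store_tracks) {
    out$tracks <- lapply(tracks, function(tr) do.call(rbind, tr))
  }
  out
}

#' Summarise dispersal distances and durations
#'
#' Mean, sample standard deviation and maximum of cumulative along-track
#' distance (km) and drift duration (days) of settled particles, plus the
#' settlement fraction.
#'
#' @param ts a [trajectory_set][run_release].
#' @return list with `n_settled`, `n_lost`, `distance` and `duration`
#'   summaries (`mean`, `sd`, `max`), and `settlement_fraction`.
#' @export
summarize_dispersal <- function(ts) {
  stopifnot(inherits(ts, "trajectory_set"))
  p <- ts$particles
  if (!nrow(p)) fail("empty trajectory set")
  s <- p[p$fate == "settled", ]
  summ <- function(x) {
    if (!length(x)) return(list(mean = NA_real_, sd = NA_real_,
                                max = NA_real_))
    list(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0,
         max = max(x))
  }
  list(n_settled = nrow(s), n_lost = sum(p$fate == "lost"),
       distance = summ(s$drift_km), duration = summ(s$drift_days),
       settlement_fraction = nrow(s) / nrow(p))
}

#' @export
print.trajectory_set <- function(x, ...) {
  p <- x$particles
  cat(sprintf("Trajectory set (year %s): %d particles from %d points\n",
              x$year, nrow(p), length(x$point_ids)))
  cat(sprintf("  settled %d (%.1f%%), lost %d\n", sum(p$fate == "settled"),
              100 * mean(p$fate == "settled"), sum(p$fate == "lost")))
  invisible(x)
}
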