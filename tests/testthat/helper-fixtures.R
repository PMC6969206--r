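# Shared small fixtures for the simulation tests.

# tiny straight-coast domain (land to the south, coast = polygon edge 3)
toy_coast <- function(length_km = 6, grid = 0.02) {
  poly <- straight_coast_polygon(length_km = length_km, lat0 = -34,
                                 lon0 = 20, land_depth_km = 10)
  build_coastal_domain(poly, grid_spacing_deg = grid, point_spacing_km = 1,
                       coast_edges = 3)
}

still_fields <- function(dom, days = 5, seed = 1) {
  generate_fields(dom, flow_recipe(mean_speed = 0, eddy_amp = 0,
                                   noise_sd = 0),
                  years = 1, days_per_year = days, seed = seed)
}

# overwrite a field series with a spatially uniform flow, land included
# (for closed-form advection checks, free of coastal shear)
uniform_fields <- function(dom, u = 0, v = 0, days = 5) {
  f <- still_fields(dom, days = days)
  f$u[] <- u
  f$v[] <- v
  f
}

# hand-built trajectory set: `fates` is a data.frame(origin_id, settle_id)
# with NA settle_id meaning lost
manual_trajectories <- function(fates, point_ids) {
  fates$fate <- ifelse(is.na(fates$settle_id), "lost", "settled")
  n <- nrow(fates)
  p <- data.frame(particle_id = seq_len(n),
                  origin_id = fates$origin_id, release_day = rep(1L, n),
                  fate = fates$fate, settle_id = fates$settle_id,
                  drift_days = rep(1, n), drift_km = rep(1, n))
  released <- as.integer(table(factor(fates$origin_id, levels = point_ids)))
  structure(list(particles = p,
                 released = stats::setNames(released, point_ids),
                 point_ids = point_ids, year = 1L,
                 capture_radius_km = 1, pld_days = 30),
            class = "trajectory_set")
}

# connectivity matrix directly from a probability matrix
cm_from_P <- function(P) {
  ids <- seq_len(nrow(P))
  dimnames(P) <- list(ids, ids)
  structure(list(point_ids = ids, P = P, released = rep(1L, nrow(P)),
                 arrivals = P, label = "manual"),
            class = "connectivity_matrix")
}

# random sub-stochastic probability matrix (row sums <= 1), some zero edges
random_prob_matrix <- function(n, density = 0.6, seed = 1) {
  set.seed(seed)
  P <- matrix(runif(n * n), n, n) * (matrix(runif(n * n), n, n) < density)
  diag(P) <- 0
  P / pmax(rowSums(P), 1) * runif(1, 0.5, 1)
}
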