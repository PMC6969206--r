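# Hourly advection, settlement and fate accounting.

test_that("bilinear interpolation reproduces constant, linear and node values", {
  dom <- toy_coast()
  f <- uniform_fields(dom, u = 0.1, v = 0, days = 2)
  iv <- interpolate_velocity(f, 20.02, -33.95, 0.2)
  expect_equal(iv$u, 0.1)
  expect_equal(iv$v, 0)

  # a field linear in lon is reproduced exactly at interior points
  a <- 0.5
  b <- -9.7
  for (d in 1:2) f$u[, , d] <- matrix(a * f$lon + b, length(f$lat),
                                      length(f$lon), byrow = TRUE)
  qlon <- c(20.013, 20.041, 20.0271)
  iv <- interpolate_velocity(f, qlon, rep(-33.95, 3), 0.2)
  expect_equal(iv$u, a * qlon + b, tolerance = 1e-12)

  # exact node value at a grid node
  iv <- interpolate_velocity(f, f$lon[3], f$lat[4], 0.2)
  expect_equal(iv$u, a * f$lon[3] + b, tolerance = 1e-12)

  # outside the grid signals out-of-domain
  iv <- interpolate_velocity(f, 99, 0, 0.2)
  expect_true(is.na(iv$u) && is.na(iv$v))
})

test_that("a forward-Euler hour step matches the m-to-degree conversion", {
  nxt <- advect(20, -34, u = 0.1, v = 0, dt_hours = 24)
  expect_equal(achconnect:::dist_km(-34, 20, nxt$lat, nxt$lon), 8.64,
               tolerance = 1e-6)
  same <- advect(20, -34, u = 0, v = 0)
  expect_equal(same$lon, 20)
  expect_equal(same$lat, -34)
  expect_error(advect(20, -34, 0.1, 0, dt_hours = 0))
})

test_that("uniform-flow displacement matches |v|*t within 0.5%", {
  big <- straight_coast_polygon(length_km = 1500, lat0 = -34, lon0 = 10,
                                land_depth_km = 30)
  dom <- build_coastal_domain(big, grid_spacing_deg = 0.08,
                              point_spacing_km = 200, coast_edges = 3)
  f <- uniform_fields(dom, u = 0.387, v = 0, days = 31)
  ts <- run_release(dom, f, release_days = 1, particles_per_point = 1,
                    pld_days = 30, capture_radius_km = 0.01,
                    precompetency_days = 31)
  # particle with > 1003 km of open water downstream (eastward)
  interior <- ts$particles[8, ]
  closed_form <- 0.387 * 86400 * 30 / 1000
  expect_lt(abs(interior$drift_km - closed_form) / closed_form, 0.005)
  expect_equal(interior$fate, "lost")
  expect_equal(interior$drift_days, 30)
})

test_that("still water with a capture zone retains every particle at its origin", {
  dom <- toy_coast()
  f <- still_fields(dom)
  ts <- run_release(dom, f, release_days = 1, pld_days = 2,
                    capture_radius_km = 1)
  expect_true(all(ts$particles$fate == "settled"))
  expect_true(all(ts$particles$settle_id == ts$particles$origin_id))
  expect_true(all(ts$particles$drift_km == 0))
})

test_that("uniform offshore flow loses every particle", {
  dom <- toy_coast()
  f <- uniform_fields(dom, u = 0, v = 0.3, days = 5)
  ts <- run_release(dom, f, release_days = 1, pld_days = 2,
                    capture_radius_km = 0.2, precompetency_days = 0.2)
  expect_true(all(ts$particles$fate == "lost"))
})

test_that("uniform onshore flow settles interior particles at nearby points", {
  dom <- toy_coast()
  f <- uniform_fields(dom, u = 0, v = -0.2, days = 5)
  ts <- run_release(dom, f, release_days = 1, pld_days = 2,
                    capture_radius_km = 0.5)
  p <- ts$particles
  interior <- p$origin_id %in% 2:6        # away from the open corners
  expect_true(all(p$fate[interior] == "settled"))
  expect_true(all(abs(p$settle_id[interior] - p$origin_id[interior]) <= 1))
})

test_that("fates are conserved per origin and runs are deterministic", {
  dom <- toy_coast()
  f <- generate_fields(dom, flow_recipe(mean_speed = 0.1, eddy_amp = 0.05,
                                        noise_sd = 0.02, onshore_speed = 0.02),
                       years = 1, days_per_year = 6, seed = 3)
  ts1 <- run_release(dom, f, release_days = 1:3, particles_per_point = 2,
                     pld_days = 2, capture_radius_km = 0.5,
                     precompetency_days = 0.25)
  ts2 <- run_release(dom, f, release_days = 1:3, particles_per_point = 2,
                     pld_days = 2, capture_radius_km = 0.5,
                     precompetency_days = 0.25)
  expect_identical(ts1, ts2)
  p <- ts1$particles
  per_origin <- table(p$origin_id)
  expect_true(all(per_origin == 2 * 3))
  expect_equal(sum(p$fate == "settled") + sum(p$fate == "lost"), nrow(p))
  expect_equal(unname(ts1$released),
               as.integer(table(factor(p$origin_id,
                                       levels = ts1$point_ids))))
})

test_that("tracks never enter the land polygon", {
  dom <- toy_coast()
  f <- generate_fields(dom, flow_recipe(mean_speed = 0.1, eddy_amp = 0.05,
                                        noise_sd = 0.05, onshore_speed = 0.05),
                       years = 1, days_per_year = 4, seed = 5)
  ts <- run_release(dom, f, release_days = 1, pld_days = 2,
                    capture_radius_km = 0.3, precompetency_days = 0.5,
                    store_tracks = TRUE)
  poly <- rbind(dom$land_polygon, dom$land_polygon[1, ])
  for (tr in ts$tracks) {
    expect_false(any(mgcv::in.out(poly, tr)))
  }
})

test_that("dispersal summaries use settled-particle track distances", {
  ts <- manual_trajectories(
    data.frame(origin_id = c(1, 1), settle_id = c(2, 2)), point_ids = 1:3)
  ts$particles$drift_km <- c(10, 30)
  ts$particles$drift_days <- c(2, 2)
  s <- summarize_dispersal(ts)
  expect_equal(s$distance$mean, 20)
  expect_equal(s$distance$sd, sqrt(200), tolerance = 1e-6)
  expect_equal(s$distance$max, 30)
  expect_equal(s$n_settled, 2)

  one <- manual_trajectories(data.frame(origin_id = 1, settle_id = 2),
                             point_ids = 1:3)
  one$particles$drift_km <- 10
  s1 <- summarize_dispersal(one)
  expect_equal(s1$distance$mean, 10)
  expect_equal(s1$distance$sd, 0)

  empty <- manual_trajectories(data.frame(origin_id = integer(0),
                                          settle_id = integer(0)),
                               point_ids = 1:3)
  expect_error(summarize_dispersal(empty), "empty")
})

test_that("retention-only runs report near-zero mean distance", {
  dom <- toy_coast()
  ts <- run_release(dom, still_fields(dom), release_days = 1, pld_days = 2,
                    capture_radius_km = 1)
  s <- summarize_dispersal(ts)
  expect_lt(s$distance$mean, 0.01)
})

test_that("an empty or out-of-span release schedule is rejected", {
  dom <- toy_coast()
  f <- still_fields(dom, days = 3)
  expect_error(run_release(dom, f, release_days = integer(0)), "empty")
  expect_error(run_release(dom, f, release_days = 99), "span")
})
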