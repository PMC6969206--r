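# One-shot dispersal pipeline on a synthetic alongshore-flow coast:
# domain -> daily fields -> particle releases -> annual connectivity
# matrices -> multi-year average -> stepping-stone probabilities between
# sampled sites -> modularity clusters, compared against the regional
# grouping implied by the flow discontinuities.

#' Run the dispersal-to-clusters pipeline on a synthetic coast
#'
#' Builds a straight east-west coastline with land to the south, drives it
#' with an eastward alongshore jet interrupted by offshore-divergence zones
#' ("flow discontinuities") at the given along-shore positions, releases
#' particles from every coastal point on the release schedule for each
#' simulated year, averages the annual connectivity matrices, computes
#' stepping-stone probabilities between `n_sites` sampled locations and
#' clusters them by modularity. The expected regional grouping (one region
#' per inter-barrier segment) is returned alongside the adjusted Rand index
#' between it and the modularity partition.
#'
#' @param coast_length_km coastline length (default 60).
#' @param barrier_positions_km along-shore positions of the flow
#'   discontinuities (default one and two thirds of the coast).
#' @param n_sites number of sampled locations, spread evenly while avoiding
#'   the barrier zones (default 9).
#' @param years independent flow years to simulate (default 2).
#' @param season_days days of fields per year (default 80).
#' @param release_every release-day stride within the first 60 days.
#' @param pld_days pelagic larval duration (default 15 at this desk scale).
#' @param mean_speed,eddy_amp,noise_sd flow-recipe parameters.
#' @param capture_radius_km,precompetency_days settlement parameters.
#' @param seed integer seed; year y uses `seed + y`.
#' @return list with `domain`, `avg` (averaged connectivity matrix),
#'   `stepping` (stepping-stone result over the sampled sites), `clusters`
#'   (modularity partition), `regions` (expected grouping), `ari`, and
#'   `dispersal` (distance/duration summary of the final year).
#' @export
run_dispersal_pipeline <- function(coast_length_km = 60,
                                   barrier_positions_km =
                                     coast_length_km * c(1, 2) / 3,
                                   n_sites = 9, years = 2, season_days = 80,
                                   release_every = 2, pld_days = 15,
                                   mean_speed = 0.15, eddy_amp = 0.04,
                                   noise_sd = 0.01,
                                   capture_radius_km = 1,
                                   precompetency_days = 0.25, seed = 1) {
  lat0 <- -34
  lon0 <- 20
  poly <- straight_coast_polygon(coast_length_km, lat0 = lat0, lon0 = lon0)
  domain <- build_coastal_domain(poly, grid_spacing_deg = 0.08,
                                 point_spacing_km = 1, coast_edges = 3)
  km_per_deg_lon <- KM_PER_DEG_LAT * cos(lat0 * pi / 180)
  barrier_lons <- lon0 + barrier_positions_km / km_per_deg_lon
  recipe <- flow_recipe(mean_speed = mean_speed, eddy_amp = eddy_amp,
                        eddy_wavelength_km = 25, eddy_period_days = 10,
                        noise_sd = noise_sd, barriers = barrier_lons,
                        barrier_width_km = 4, barrier_speed = 0.3,
                        onshore_speed = 0.03, offshore_sign = 1,
                        name = "alongshore-barriers-v1")

  yearly <- vector("list", years)
  ts <- NULL
  for (y in seq_len(years)) {
    fields <- generate_fields(domain, recipe, years = 1,
                              days_per_year = season_days, seed = seed + y)
    ts <- run_release(domain, fields,
                      release_days = seq(1, season_days - pld_days,
                                         by = release_every),
                      particles_per_point = 1, pld_days = pld_days,
                      capture_radius_km = capture_radius_km,
                      precompetency_days = precompetency_days, year = y)
    yearly[[y]] <- build_matrix(ts)
  }
  avg <- average_matrices(yearly)

  # sampled locations: evenly spread, kept clear of the barrier zones; the
  # expected region of a site is the inter-barrier segment it falls in
  cp <- domain$coastal_points
  brk <- c(0, sort(barrier_positions_km), coast_length_km)
  nseg <- length(brk) - 1
  counts <- diff(floor(seq(0, n_sites, length.out = nseg + 1)))
  sampled <- integer(0)
  region <- character(0)
  for (s in seq_len(nseg)) {
    lo <- brk[s] + 6
    hi <- brk[s + 1] - 6
    pos <- seq(lo, hi, length.out = max(counts[s], 1))
    ids <- vapply(pos, function(p) cp$id[which.min(abs(cp$along_km - p))],
                  numeric(1))
    sampled <- c(sampled, ids)
    region <- c(region, rep(paste0("R", s), length(ids)))
  }
  names(region) <- as.character(sampled)

  ss <- stepping_stone(avg, sampled_ids = sampled)
  cl <- cluster_modularity(ss$prob, sampled_ids = as.character(sampled),
                           exhaustive_max = 10)
  cmp <- compare_clusterings(region, cl)
  list(domain = domain, avg = avg, stepping = ss, clusters = cl,
       regions = region, ari = cmp$ari, dispersal = summarize_dispersal(ts))
}

#' Run the genetics-to-verdict pipeline for one simulated scenario
#'
#' Simulates haplotype and microsatellite data for a
#' [population_scenario()], computes rarefied allelic richness (bootstrap
#' CIs), per-site haplotype diversity with pairwise permutation
#' difference tests (within lineages), and pairwise F_ST (point values),
#' then evaluates the centre-versus-edge prediction with [evaluate_ach()].
#'
#' @param sc a [population_scenario()].
#' @param loci microsatellite loci to simulate (default 10).
#' @param ar_bootstraps bootstrap replicates for allelic richness.
#' @param dd_iterations iterations per diversity-difference test.
#' @param seed seed for the analysis-stage resampling (bootstraps and
#'   permutations); the data are governed by `sc$seed`.
#' @return list with `diversity` (per-site table), `pairwise_p`,
#'   `fst`, and `verdict` (an [evaluate_ach()] result).
#' @export
run_genetics_pipeline <- function(sc, loci = 10, ar_bootstraps = 300,
                                  dd_iterations = 1000, seed = 1) {
  stopifnot(inherits(sc, "population_scenario"))
  gt <- simulate_genotypes(sc, loci = loci)
  hs <- simulate_haplotypes(sc)
  ar <- allelic_richness(gt, bootstraps = ar_bootstraps, seed = seed)
  hdiv <- do.call(rbind, lapply(hs, haplotype_diversity))
  codes <- sc$sites$code
  pmat <- matrix(NA_real_, length(codes), length(codes),
                 dimnames = list(codes, codes))
  with_seed(seed + 1L, {
    for (i in seq_along(codes)[-length(codes)]) {
      for (j in (i + 1):length(codes)) {
        if (sc$sites$lineage[i] != sc$sites$lineage[j]) next
        dt <- diversity_diff_test(hs[[i]], hs[[j]],
                                  iterations = dd_iterations)
        pmat[i, j] <- pmat[j, i] <- dt$p_h
      }
    }
  })
  fst <- fst_microsat(gt, permutations = 0)
  verdict <- evaluate_ach(rbind(ar, hdiv), sc$sites,
                          pairwise_p = list(h = pmat), diff = fst)
  list(diversity = rbind(ar, hdiv), pairwise_p = list(h = pmat),
       fst = fst, verdict = verdict)
}
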