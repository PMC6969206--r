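# Plain-text interchange: FASTA per site, GenAlEx-like genotype CSV (two
# columns per locus, repeat units in the header), square/edge-list
# connectivity CSV, GeoJSON + CSV for domains, long-format CSV for velocity
# fields.

#' Read and write per-site FASTA haplotype files
#'
#' @param hs a [haplotype_set()].
#' @param path file path.
#' @param site site code to attach on read (default: file name).
#' @return `read_haplotype_fasta` returns a [haplotype_set()].
#' @export
write_haplotype_fasta <- function(hs, path) {
  stopifnot(inherits(hs, "haplotype_set"))
  seqs <- strsplit(hs$sequences, "")
  names(seqs) <- sprintf("%s_%03d", hs$site, seq_along(seqs))
  ape::write.dna(seqs, path, format = "fasta", colsep = "")
  invisible(path)
}

#' @rdname write_haplotype_fasta
#' @export
read_haplotype_fasta <- function(path, site = NULL) {
  d <- ape::read.dna(path, format = "fasta", as.character = TRUE,
                     as.matrix = FALSE)
  seqs <- toupper(vapply(d, paste, "", collapse = ""))
  if (is.null(site)) site <- sub("\\.[^.]*$", "", basename(path))
  haplotype_set(unname(seqs), site = site)
}

#' Read and write genotype tables as GenAlEx-like CSV
#'
#' Layout: columns `site`, `ind`, then two columns per locus named
#' `<locus>(<repeat unit>)`. Missing calls are empty cells.
#'
#' @param gt a [genotype_table()].
#' @param path file path.
#' @return `read_genotype_csv` returns a [genotype_table()].
#' @export
write_genotype_csv <- function(gt, path) {
  stopifnot(inherits(gt, "genotype_table"))
  n <- dim(gt$alleles)[1]
  nl <- dim(gt$alleles)[2]
  df <- data.frame(site = gt$site, ind = seq_len(n))
  for (l in seq_len(nl)) {
    nm <- sprintf("%s(%g)", gt$loci[l], gt$repeat_units[l])
    df[[paste0(nm, ".a")]] <- gt$alleles[, l, 1]
    df[[paste0(nm, ".b")]] <- gt$alleles[, l, 2]
  }
  names(df)[-(1:2)] <- rep(sprintf("%s(%g)", gt$loci, gt$repeat_units),
                           each = 2)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_genotype_csv
#' @export
read_genotype_csv <- function(path) {
  hdr <- strsplit(readLines(path, n = 1), ",")[[1]]
  hdr <- gsub("\"", "", hdr)
  df <- utils::read.csv(path, check.names = FALSE)
  lcols <- which(grepl("\\(.*\\)", hdr))
  lnames <- unique(hdr[lcols])
  loci <- sub("\\(.*", "", lnames)
  ru <- as.numeric(sub(".*\\(([^)]*)\\).*", "\\1", lnames))
  n <- nrow(df)
  alleles <- array(NA_integer_, c(n, length(loci), 2))
  for (l in seq_along(lnames)) {
    cols <- lcols[hdr[lcols] == lnames[l]]
    alleles[, l, 1] <- as.integer(df[[cols[1]]])
    alleles[, l, 2] <- as.integer(df[[cols[2]]])
  }
  genotype_table(alleles, df$site, loci = loci, repeat_units = ru)
}

#' Write a connectivity matrix as square CSV and as an edge list
#'
#' @param cm a [connectivity_matrix][build_matrix].
#' @param path path for the square CSV (header = point ids).
#' @param edge_path optional path for an `(i, j, P)` edge list of the
#'   non-zero entries.
#' @export
write_connectivity_csv <- function(cm, path, edge_path = NULL) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  utils::write.csv(as.data.frame(cm$P), path, row.names = TRUE)
  if (!is.null(edge_path)) {
    nz <- which(cm$P > 0, arr.ind = TRUE)
    utils::write.csv(data.frame(i = cm$point_ids[nz[, 1]],
                                j = cm$point_ids[nz[, 2]],
                                P = cm$P[nz]),
                     edge_path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_connectivity_csv
#' @export
read_connectivity_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  P <- as.matrix(df)
  ids <- rownames(P)
  structure(list(point_ids = ids, P = P, released = NULL, arrivals = NULL,
                 label = "file"),
            class = "connectivity_matrix")
}

#' Write particle fates as CSV
#'
#' @param ts a [trajectory_set][run_release].
#' @param path file path.
#' @export
write_trajectories_csv <- function(ts, path) {
  stopifnot(inherits(ts, "trajectory_set"))
  utils::write.csv(ts$particles, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write and read a coastal domain (GeoJSON polygon + coastal-point CSV)
#'
#' @param domain a [coastal_domain][build_coastal_domain].
#' @param dir output directory; writes `polygon.geojson` and
#'   `coastal_points.csv`.
#' @export
write_domain <- function(domain, dir) {
  stopifnot(inherits(domain, "coastal_domain"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ring <- rbind(domain$land_polygon, domain$land_polygon[1, ])
  gj <- list(type = "Feature",
             geometry = list(type = "Polygon",
                             coordinates = list(lapply(seq_len(nrow(ring)),
                                                       function(i) ring[i, ]))),
             properties = list(grid_spacing_deg = domain$grid_spacing_deg,
                               point_spacing_km = domain$point_spacing_km))
  jsonlite::write_json(gj, file.path(dir, "polygon.geojson"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(domain$coastal_points,
                   file.path(dir, "coastal_points.csv"), row.names = FALSE)
  invisible(dir)
}

#' Write and read a velocity-field series as long-format CSV
#'
#' Columns `time`, `lat`, `lon`, `u`, `v`; the seed and recipe go to a JSON
#' sidecar `<path>.json`.
#'
#' @param fields a [velocity_fields][generate_fields].
#' @param path CSV path.
#' @export
write_fields_csv <- function(fields, path) {
  stopifnot(inherits(fields, "velocity_fields"))
  grid <- expand.grid(lat = fields$lat, lon = fields$lon)
  rows <- do.call(rbind, lapply(fields$times, function(t) {
    data.frame(time = t, lat = grid$lat, lon = grid$lon,
               u = as.vector(fields$u[, , t]), v = as.vector(fields$v[, , t]))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  jsonlite::write_json(list(seed = fields$seed,
                            recipe = unclass(fields$recipe),
                            days_per_year = fields$days_per_year),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fields_csv
#' @export
read_fields_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  lat <- sort(unique(df$lat))
  lon <- sort(unique(df$lon))
  times <- sort(unique(df$time))
  u <- array(0, c(length(lat), length(lon), length(times)))
  v <- array(0, c(length(lat), length(lon), length(times)))
  ri <- match(df$lat, lat)
  ci <- match(df$lon, lon)
  ti <- match(df$time, times)
  u[cbind(ri, ci, ti)] <- df$u
  v[cbind(ri, ci, ti)] <- df$v
  recipe <- do.call(flow_recipe, meta$recipe[names(meta$recipe) != ""])
  structure(list(times = times,
                 year = rep(1L, length(times)), lat = lat, lon = lon,
                 u = u, v = v, seed = meta$seed, recipe = recipe,
                 days_per_year = meta$days_per_year),
            class = "velocity_fields")
}
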