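# Synthetic population-genetic data: centre and edge sites from two
# divergent lineages, with a switchable centre-edge ("abundant centre")
# effect that lowers diversity and migration at range edges.
#
# No coalescent machinery: site samples are frequency draws from
# lineage-level haplotype/allele pools, which makes target diversities
# exactly calibratable (the unbiased gene-diversity estimator has
# expectation 1 - sum(p^2), so a frequency vector can be solved for any
# attainable target h).

#' Describe a centre/edge population scenario
#'
#' @param sites data frame with columns `code`, `lineage`, `category`
#'   (`"centre"` or `"edge"`) and `n` (sample size, >= 2); default is a
#'   balanced two-lineage design with two centre and two edge sites per
#'   lineage and n = 45.
#' @param centre_h target haplotype diversity at centre sites.
#' @param hap_pool haplotypes per lineage pool.
#' @param seq_length alignment length, bp.
#' @param mut_rate mean substitutions separating a derived haplotype from
#'   its lineage base (sets the nucleotide-diversity scale).
#' @param divergence fixed differences between the two lineage base
#'   haplotypes.
#' @param allele_pool distinct microsatellite alleles per locus at centre
#'   sites.
#' @param msat_divergence offset (in repeat counts) between the lineages'
#'   allele windows.
#' @param repeat_unit microsatellite repeat unit length, bp.
#' @param ach_effect if TRUE, edge sites get `edge_multiplier` times the
#'   centre diversity (haplotype target and allele-pool size) and
#'   `edge_multiplier` times the migration rate.
#' @param edge_multiplier edge diversity/migration multiplier in (0, 1].
#' @param migration probability that an individual is drawn from an
#'   adjacent site's pool instead of its own.
#' @param missing_rate per-genotype missing-data probability.
#' @param seed integer RNG seed.
#' @return a `population_scenario`.
#' @export
population_scenario <- function(sites = default_scenario_sites(),
                                centre_h = 0.85, hap_pool = 12,
                                seq_length = 600, mut_rate = 3,
                                divergence = 12, allele_pool = 12,
                                msat_divergence = 6, repeat_unit = 2,
                                ach_effect = FALSE, edge_multiplier = 0.5,
                                migration = 0.05, missing_rate = 0.02,
                                seed = 1) {
  sites <- as.data.frame(sites)
  stopifnot(all(c("code", "lineage", "category", "n") %in% names(sites)),
            all(sites$n >= 2),
            all(sites$category %in% c("centre", "edge")),
            edge_multiplier > 0, edge_multiplier <= 1,
            migration >= 0, migration <= 1,
            missing_rate >= 0, missing_rate < 1,
            hap_pool >= 2, allele_pool >= 1, seq_length > divergence)
  structure(list(sites = sites, centre_h = centre_h, hap_pool = hap_pool,
                 seq_length = seq_length, mut_rate = mut_rate,
                 divergence = divergence, allele_pool = allele_pool,
                 msat_divergence = msat_divergence,
                 repeat_unit = repeat_unit, ach_effect = ach_effect,
                 edge_multiplier = edge_multiplier, migration = migration,
                 missing_rate = missing_rate, seed = seed),
            class = "population_scenario")
}

#' @rdname population_scenario
#' @export
default_scenario_sites <- function() {
  data.frame(
    code = c("W1", "W2", "W3", "W4", "E1", "E2", "E3", "E4"),
    lineage = rep(c("west", "east"), each = 4),
    category = c("edge", "centre", "centre", "edge",
                 "edge", "centre", "centre", "edge"),
    n = 45)
}

#' @export
print.population_scenario <- function(x, ...) {
  cat(sprintf("Population scenario: %d sites, 2 x %d-haplotype pools, ACH %s\n",
              nrow(x$sites), x$hap_pool,
              if (x$ach_effect) sprintf("on (x%.2f at edges)",
                                        x$edge_multiplier) else "off"))
  invisible(x)
}

# frequency vector over K pool members with sum(p^2) = 1 - h_target and a
# chosen dominant member; errors when the target is unattainable
calibrated_freqs <- function(h_target, K, dominant = 1) {
  if (h_target < 0 || h_target > 1 - 1 / K + 1e-12) {
    fail(sprintf("target h = %.3f unattainable with a pool of %d", h_target, K))
  }
  A <- K / (K - 1)
  B <- -2 / (K - 1)
  C <- 1 / (K - 1) - (1 - h_target)
  a <- (-B + sqrt(max(B^2 - 4 * A * C, 0))) / (2 * A)
  p <- rep((1 - a) / (K - 1), K)
  p[dominant] <- a
  p / sum(p)
}

random_sequence <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

mutate_sequence <- function(seq, positions) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (pos in positions) {
    s[pos] <- sample(setdiff(c("A", "C", "G", "T"), s[pos]), 1)
  }
  paste(s, collapse = "")
}

# star-like pool: lineage base plus derived haplotypes with Poisson numbers
# of substitutions
build_hap_pool <- function(base, K, mut_rate) {
  pool <- base
  L <- nchar(base)
  while (length(pool) < K) {
    nmut <- max(1, stats::rpois(1, mut_rate))
    cand <- mutate_sequence(base, sample.int(L, min(nmut, L)))
    if (!cand %in% pool) pool <- c(pool, cand)
  }
  pool
}

site_h_target <- function(sc, category) {
  if (sc$ach_effect && category == "edge") {
    sc$centre_h * sc$edge_multiplier
  } else {
    sc$centre_h
  }
}

site_migration <- function(sc, category) {
  if (sc$ach_effect && category == "edge") {
    sc$migration * sc$edge_multiplier
  } else {
    sc$migration
  }
}

#' Simulate per-site haplotype samples
#'
#' Builds a star-like haplotype pool per lineage (a base haplotype plus
#' Poisson-mutated variants; the two bases differ at `divergence` fixed
#' positions), assigns each site a frequency vector solved so the expected
#' unbiased haplotype diversity equals the site's target, and draws the
#' site's sample from it. The dominant haplotype rotates across the sites of
#' a lineage, creating among-site structure. With probability equal to the
#' migration rate an individual is drawn from an adjacent site instead.
#'
#' @param sc a [population_scenario()].
#' @return named list of [haplotype_set()] objects, one per site.
#' @export
simulate_haplotypes <- function(sc) {
  stopifnot(inherits(sc, "population_scenario"))
  with_seed(sc$seed, {
    lineages <- unique(sc$sites$lineage)
    base1 <- random_sequence(sc$seq_length)
    bases <- list(base1)
    if (length(lineages) > 1) {
      div_pos <- sample.int(sc$seq_length, sc$divergence)
      bases[[2]] <- mutate_sequence(base1, div_pos)
    }
    names(bases) <- lineages[seq_along(bases)]
    pools <- lapply(bases, build_hap_pool, K = sc$hap_pool,
                    mut_rate = sc$mut_rate)

    ns <- nrow(sc$sites)
    freqs <- vector("list", ns)
    for (s in seq_len(ns)) {
      lin <- sc$sites$lineage[s]
      rank_in_lin <- sum(sc$sites$lineage[seq_len(s)] == lin)
      freqs[[s]] <- calibrated_freqs(
        site_h_target(sc, sc$sites$category[s]), sc$hap_pool,
        dominant = (rank_in_lin - 1) %% sc$hap_pool + 1)
    }

    out <- vector("list", ns)
    for (s in seq_len(ns)) {
      n <- sc$sites$n[s]
      m <- site_migration(sc, sc$sites$category[s])
      src <- rep(s, n)
      if (m > 0 && ns > 1) {
        mig <- stats::runif(n) < m
        nb <- s + sample(c(-1L, 1L), n, TRUE)
        nb[nb < 1L] <- 2L
        nb[nb > ns] <- ns - 1L
        src[mig] <- nb[mig]
      }
      seqs <- character(n)
      for (i in seq_len(n)) {
        pool <- pools[[sc$sites$lineage[src[i]]]]
        seqs[i] <- pool[sample.int(sc$hap_pool, 1, prob = freqs[[src[i]]])]
      }
      out[[s]] <- haplotype_set(seqs, site = sc$sites$code[s],
                                lineage = sc$sites$lineage[src])
    }
    names(out) <- sc$sites$code
    out
  })
}

#' Simulate a diploid microsatellite genotype table
#'
#' Each site gets, per locus, a window of consecutive repeat-count alleles
#' (the two lineages' windows are offset by `msat_divergence`; edge windows
#' shrink by `edge_multiplier` when the centre-edge effect is on) and a
#' frequency vector drawn from a symmetric Dirichlet. Individuals are two
#' independent allele draws per locus (Hardy-Weinberg by construction), with
#' migrant individuals drawn from an adjacent site and whole genotypes set
#' missing at `missing_rate`. Alleles are stored as fragment sizes
#' (`100 + repeat_unit * count`).
#'
#' @param sc a [population_scenario()].
#' @param loci number of loci (default 10).
#' @return a [genotype_table()].
#' @export
simulate_genotypes <- function(sc, loci = 10) {
  stopifnot(inherits(sc, "population_scenario"))
  if (loci < 1) fail("loci must be >= 1")
  with_seed(sc$seed + 1L, {
    ns <- nrow(sc$sites)
    lineages <- unique(sc$sites$lineage)
    pool_of <- function(s) {
      K <- sc$allele_pool
      if (sc$ach_effect && sc$sites$category[s] == "edge") {
        K <- max(1, ceiling(K * sc$edge_multiplier))
      }
      K
    }
    # per site x locus: allele windows (repeat counts) and Dirichlet freqs
    windows <- vector("list", ns)
    freqs <- vector("list", ns)
    for (s in seq_len(ns)) {
      lin_off <- (match(sc$sites$lineage[s], lineages) - 1) *
        sc$msat_divergence
      K <- pool_of(s)
      windows[[s]] <- lapply(seq_len(loci), function(l) {
        start <- 10 + lin_off + (l - 1) %% 3   # slight per-locus stagger
        seq(start, length.out = K)
      })
      freqs[[s]] <- lapply(seq_len(loci), function(l) {
        g <- stats::rgamma(K, 1)
        g / sum(g)
      })
    }
    ntot <- sum(sc$sites$n)
    alleles <- array(NA_integer_, c(ntot, loci, 2))
    site_vec <- character(ntot)
    row <- 0L
    for (s in seq_len(ns)) {
      n <- sc$sites$n[s]
      m <- site_migration(sc, sc$sites$category[s])
      src <- rep(s, n)
      if (m > 0 && ns > 1) {
        mig <- stats::runif(n) < m
        nb <- s + sample(c(-1L, 1L), n, TRUE)
        nb[nb < 1L] <- 2L
        nb[nb > ns] <- ns - 1L
        src[mig] <- nb[mig]
      }
      for (i in seq_len(n)) {
        row <- row + 1L
        site_vec[row] <- sc$sites$code[s]
        for (l in seq_len(loci)) {
          if (stats::runif(1) < sc$missing_rate) next
          w <- windows[[src[i]]][[l]]
          f <- freqs[[src[i]]][[l]]
          cnt <- w[sample.int(length(w), 2, replace = TRUE, prob = f)]
          alleles[row, l, ] <- as.integer(100 + sc$repeat_unit * cnt)
        }
      }
    }
    genotype_table(alleles, site_vec, loci = paste0("L", seq_len(loci)),
                   repeat_units = rep(sc$repeat_unit, loci))
  })
}
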