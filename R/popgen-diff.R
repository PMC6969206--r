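# Pairwise genetic differentiation: AMOVA-based Phi_PT for haplotype data,
# Nei F_ST and Hedrick's G''_ST for microsatellites, each with a
# shuffle-individuals permutation test and Bonferroni-adjusted p-values.

diff_matrix <- function(statistic, sites, value, p, permutations, note = NULL) {
  m <- sum(lower.tri(value))          # number of pairwise tests
  p_adj <- p
  p_adj[] <- pmin(1, m * as.vector(p))
  diag(p_adj) <- NA
  structure(list(statistic = statistic, sites = sites, value = value,
                 p = p, p_adj = p_adj, permutations = permutations,
                 note = note),
            class = "diff_matrix")
}

#' @export
print.diff_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("Pairwise %s (%d permutations)\n", x$statistic,
              x$permutations))
  v <- round(x$value, digits)
  v[upper.tri(v)] <- round(x$p_adj[upper.tri(x$p_adj)], digits)
  cat("  (lower triangle: statistic; upper: Bonferroni-adjusted p)\n")
  print(v)
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

# AMOVA variance components from a squared-distance matrix D2 and a group
# factor. Pairwise difference counts are used directly as squared distances
# (the convention for haplotype-level AMOVA).
amova_phi <- function(D2, grp) {
  grp <- as.integer(grp)
  N <- length(grp)
  k <- length(unique(grp))
  ss_total <- sum(D2) / (2 * N)
  ss_within <- 0
  sizes <- numeric(k)
  for (g in seq_len(k)) {
    sel <- grp == g
    sizes[g] <- sum(sel)
    ss_within <- ss_within + sum(D2[sel, sel]) / (2 * sizes[g])
  }
  ss_among <- ss_total - ss_within
  df_a <- k - 1
  df_w <- N - k
  ms_a <- ss_among / df_a
  ms_w <- ss_within / df_w
  n0 <- (N - sum(sizes^2) / N) / df_a
  sigma_a <- (ms_a - ms_w) / n0
  sigma_w <- ms_w
  tot <- sigma_a + sigma_w
  if (tot <= 0) return(0)
  sigma_a / tot
}

#' Pairwise Phi_PT from haplotype data (AMOVA)
#'
#' The molecular analogue of F_ST: the fraction of molecular variance among
#' populations, computed per site pair from an analysis of molecular
#' variance on the matrix of pairwise nucleotide-difference counts
#' (pairwise deletion of missing positions). Significance is assessed by
#' shuffling individuals between the two sites; negative values are reported
#' as computed.
#'
#' @param sets list of [haplotype_set()] objects (>= 2 sites). Sites with
#'   fewer than 2 sequences are dropped with a warning.
#' @param permutations permutation count (default 999).
#' @param seed RNG seed.
#' @return a `diff_matrix` with pairwise values, raw and Bonferroni-adjusted
#'   permutation p-values.
#' @export
phi_pt <- function(sets, permutations = 999, seed = NULL) {
  stopifnot(is.list(sets), all(vapply(sets, inherits, TRUE, "haplotype_set")))
  small <- vapply(sets, function(s) length(s$sequences) < 2, TRUE)
  if (any(small)) {
    warning("dropping sites with n < 2: ",
            paste(vapply(sets[small], `[[`, "", "site"), collapse = ", "))
    sets <- sets[!small]
  }
  if (length(sets) < 2) fail("need at least two sites with n >= 2")
  sites <- vapply(sets, `[[`, "", "site")
  k <- length(sets)
  value <- p <- matrix(0, k, k, dimnames = list(sites, sites))
  diag(p) <- NA
  with_seed(seed, {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        n1 <- length(sets[[i]]$sequences)
        n2 <- length(sets[[j]]$sequences)
        pooled <- c(sets[[i]]$sequences, sets[[j]]$sequences)
        hd <- hap_distances(pooled)
        D2 <- hd$diffs[hd$id, hd$id]
        grp <- rep(1:2, c(n1, n2))
        obs <- amova_phi(D2, grp)
        hits <- 0L
        for (it in seq_len(permutations)) {
          hits <- hits +
            (amova_phi(D2, grp[sample.int(n1 + n2)]) >= obs - 1e-12)
        }
        value[i, j] <- value[j, i] <- obs
        p[i, j] <- p[j, i] <- (hits + 1) / (permutations + 1)
      }
    }
  })
  diff_matrix("Phi_PT", sites, value, p, permutations)
}

# --- microsatellite heterozygosity machinery ---------------------------------

# For one pair of populations: averaged-across-loci H_S and H_T
# (frequency-based, pairwise-available-case for missing data, populations
# weighted equally).
het_components <- function(codes, nall, grp) {
  hs_sum <- 0
  ht_sum <- 0
  used <- 0L
  for (l in seq_along(codes)) {
    cl <- codes[[l]]                 # (2n) integer codes, NA = missing
    g <- rep(grp, 2L)
    ok <- !is.na(cl)
    if (!any(ok & g == 1L) || !any(ok & g == 2L)) next
    c1 <- tabulate(cl[ok & g == 1L], nall[l])
    c2 <- tabulate(cl[ok & g == 2L], nall[l])
    p1 <- c1 / sum(c1)
    p2 <- c2 / sum(c2)
    hs <- 1 - (sum(p1^2) + sum(p2^2)) / 2
    pbar <- (p1 + p2) / 2
    ht <- 1 - sum(pbar^2)
    hs_sum <- hs_sum + hs
    ht_sum <- ht_sum + ht
    used <- used + 1L
  }
  if (used == 0L) return(c(HS = NA_real_, HT = NA_real_))
  c(HS = hs_sum / used, HT = ht_sum / used)
}

pairwise_microsat <- function(gt, stat, permutations, seed) {
  stopifnot(inherits(gt, "genotype_table"))
  sites <- unique(gt$site)
  if (length(sites) < 2) fail("need at least two sites")
  nl <- dim(gt$alleles)[2]
  k <- length(sites)
  value <- p <- matrix(0, k, k, dimnames = list(sites, sites))
  diag(p) <- NA
  notes <- character(0)

  stat_of <- function(h) {
    if (is.na(h["HS"])) return(NA_real_)
    HS <- h[["HS"]]; HT <- h[["HT"]]
    if (stat == "fst") {
      if (HT <= 0) return(0)
      (HT - HS) / HT
    } else {                        # Hedrick's G''_ST, k = 2 populations
      if (HS >= 1) return(NA_real_)
      if (HT <= 0) return(0)
      2 * (HT - HS) / ((2 * HT - HS) * (1 - HS))
    }
  }

  with_seed(seed, {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        idx <- which(gt$site %in% sites[c(i, j)])
        grp <- ifelse(gt$site[idx] == sites[i], 1L, 2L)
        n <- length(idx)
        # per-locus integer allele codes over the pooled pair
        codes <- vector("list", nl)
        nall <- integer(nl)
        for (l in seq_len(nl)) {
          a <- c(gt$alleles[idx, l, 1], gt$alleles[idx, l, 2])
          u <- sort(unique(a[!is.na(a)]))
          codes[[l]] <- match(a, u)
          nall[l] <- length(u)
        }
        obs <- stat_of(het_components(codes, nall, grp))
        hits <- 0L
        if (permutations > 0 && !is.na(obs)) {
          for (it in seq_len(permutations)) {
            perm <- stat_of(het_components(codes, nall, grp[sample.int(n)]))
            hits <- hits + (!is.na(perm) && perm >= obs - 1e-12)
          }
          p[i, j] <- p[j, i] <- (hits + 1) / (permutations + 1)
        } else {
          p[i, j] <- p[j, i] <- NA_real_
        }
        if (is.na(obs)) {
          notes <- c(notes, sprintf("%s-%s: undefined (H_S = 1)",
                                    sites[i], sites[j]))
        } else if (obs == 0 && stat == "fst") {
          h <- het_components(codes, nall, grp)
          if (!is.na(h[["HT"]]) && h[["HT"]] <= 0) {
            notes <- c(notes, sprintf("%s-%s: monomorphic pair (H_T = 0)",
                                      sites[i], sites[j]))
          }
        }
        value[i, j] <- value[j, i] <- obs
      }
    }
  })
  diff_matrix(if (stat == "fst") "F_ST" else "G''_ST", sites, value, p,
              permutations,
              note = if (length(notes)) paste(notes, collapse = "; "))
}

#' Pairwise F_ST for microsatellite data
#'
#' Nei's frequency-based form: per locus, \eqn{H_S} is the mean expected
#' heterozygosity of the two populations and \eqn{H_T} the expected
#' heterozygosity of their unweighted mean allele frequencies; \eqn{H_S} and
#' \eqn{H_T} are averaged across loci before forming
#' \eqn{F_{ST} = (H_T - H_S)/H_T}. Missing calls are handled
#' pairwise-available-case. Monomorphic pairs (\eqn{H_T = 0}) get value 0
#' with a note. Significance by shuffling individuals between the pair.
#'
#' @param gt a [genotype_table()] covering >= 2 sites.
#' @param permutations permutation count (default 999); 0 skips the test.
#' @param seed RNG seed.
#' @return a `diff_matrix`.
#' @export
fst_microsat <- function(gt, permutations = 999, seed = NULL) {
  pairwise_microsat(gt, "fst", permutations, seed)
}

#' Pairwise G''_ST for microsatellite data
#'
#' Hedrick's standardised differentiation statistic, suited to highly
#' polymorphic markers:
#' \deqn{G''_{ST} = \frac{k(H_T - H_S)}{(k H_T - H_S)(1 - H_S)}}
#' with \eqn{k = 2} populations per pairwise comparison and \eqn{H_S},
#' \eqn{H_T} averaged across loci as in [fst_microsat()]. Undefined when
#' \eqn{H_S = 1} (reported as `NA`).
#'
#' @inheritParams fst_microsat
#' @return a `diff_matrix`.
#' @export
g_double_prime_st <- function(gt, permutations = 999, seed = NULL) {
  pairwise_microsat(gt, "gppst", permutations, seed)
}
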