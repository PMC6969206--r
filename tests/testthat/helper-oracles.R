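# Independent brute-force oracles: naive double loops and exhaustive
# enumeration, deliberately sharing no code with the package internals.

# naive sequence mismatch count / comparable sites with pairwise deletion
oracle_seq_diff <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  c(diff = sum(a[ok] != b[ok]), sites = sum(ok))
}

oracle_h <- function(seqs) {
  n <- length(seqs)
  cnt <- table(seqs)
  p <- cnt / n
  n / (n - 1) * (1 - sum(p^2))
}

oracle_pi <- function(seqs) {
  n <- length(seqs)
  tot <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      d <- oracle_seq_diff(seqs[i], seqs[j])
      tot <- tot + d["diff"] / d["sites"]
    }
  }
  unname(tot / choose(n, 2))
}

# hand-computed AMOVA table on difference counts treated as squared distances
oracle_phi <- function(seqs1, seqs2) {
  all_seqs <- c(seqs1, seqs2)
  n <- length(all_seqs)
  D2 <- matrix(0, n, n)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      D2[i, j] <- D2[j, i] <- oracle_seq_diff(all_seqs[i], all_seqs[j])["diff"]
    }
  }
  g <- rep(1:2, c(length(seqs1), length(seqs2)))
  sst <- sum(D2) / (2 * n)
  ssw <- 0
  for (k in 1:2) {
    idx <- which(g == k)
    ssw <- ssw + sum(D2[idx, idx]) / (2 * length(idx))
  }
  ssa <- sst - ssw
  msa <- ssa / 1
  msw <- ssw / (n - 2)
  n0 <- (n - (length(seqs1)^2 + length(seqs2)^2) / n) / 1
  va <- (msa - msw) / n0
  vw <- msw
  if (va + vw <= 0) return(0)
  va / (va + vw)
}

# allele frequencies of one population at one locus (naive)
oracle_freqs <- function(alle) {
  a <- alle[!is.na(alle)]
  tab <- table(a)
  as.numeric(tab) / length(a)
}

# per-pair H_S / H_T averaged over loci, then the F_ST and G''_ST ratios
oracle_het <- function(gt, s1, s2) {
  i1 <- which(gt$site == s1)
  i2 <- which(gt$site == s2)
  hs <- ht <- c()
  for (l in seq_along(gt$loci)) {
    a1 <- c(gt$alleles[i1, l, 1], gt$alleles[i1, l, 2])
    a2 <- c(gt$alleles[i2, l, 1], gt$alleles[i2, l, 2])
    if (all(is.na(a1)) || all(is.na(a2))) next
    u <- sort(unique(c(a1[!is.na(a1)], a2[!is.na(a2)])))
    p1 <- sapply(u, function(x) mean(a1[!is.na(a1)] == x))
    p2 <- sapply(u, function(x) mean(a2[!is.na(a2)] == x))
    hs <- c(hs, 1 - (sum(p1^2) + sum(p2^2)) / 2)
    ht <- c(ht, 1 - sum(((p1 + p2) / 2)^2))
  }
  c(HS = mean(hs), HT = mean(ht))
}

oracle_fst <- function(gt, s1, s2) {
  h <- oracle_het(gt, s1, s2)
  if (h["HT"] <= 0) return(0)
  unname((h["HT"] - h["HS"]) / h["HT"])
}

oracle_gppst <- function(gt, s1, s2) {
  h <- oracle_het(gt, s1, s2)
  if (h["HS"] >= 1) return(NA_real_)
  if (h["HT"] <= 0) return(0)
  unname(2 * (h["HT"] - h["HS"]) / ((2 * h["HT"] - h["HS"]) * (1 - h["HS"])))
}

oracle_ar <- function(gt, site) {
  idx <- which(gt$site == site)
  mean(sapply(seq_along(gt$loci), function(l) {
    a <- c(gt$alleles[idx, l, 1], gt$alleles[idx, l, 2])
    length(unique(a[!is.na(a)]))
  }))
}

# Bruvo distance between two complete diploid genotypes in repeat units,
# enumerating both pairings explicitly
oracle_bruvo_geno <- function(a, b) {
  d <- function(x, y) 1 - 2^(-abs(x - y))
  min(mean(c(d(a[1], b[1]), d(a[2], b[2]))),
      mean(c(d(a[1], b[2]), d(a[2], b[1]))))
}

# exhaustive max-product path probability between every ordered pair by
# depth-first enumeration of all simple paths
oracle_maxprod <- function(P) {
  n <- nrow(P)
  best <- matrix(0, n, n)
  diag(best) <- 1
  rec <- function(path, prob, target) {
    cur <- path[length(path)]
    if (cur == target) {
      if (prob > best[path[1], target]) best[path[1], target] <<- prob
      return()
    }
    for (nxt in seq_len(n)) {
      if (nxt %in% path || P[cur, nxt] <= 0) next
      rec(c(path, nxt), prob * P[cur, nxt], target)
    }
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) rec(i, 1, j)
    }
  }
  best
}

# all partitions of 1..n by recursive block assignment (independent of the
# package's restricted-growth-string enumerator)
oracle_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in oracle_partitions(n - 1)) {
    k <- max(p)
    for (b in seq_len(k + 1)) out[[length(out) + 1]] <- c(p, b)
  }
  out
}

oracle_best_modularity <- function(A) {
  best_q <- -Inf
  best <- NULL
  for (p in oracle_partitions(nrow(A))) {
    q <- directed_modularity(A, p)
    if (q > best_q + 1e-12) {
      best_q <- q
      best <- p
    }
  }
  list(Q = best_q, membership = best)
}

# adjusted Rand index straight from the contingency-table formula
oracle_ari <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * cc / choose(n, 2)
  maxi <- (b + cc) / 2
  if (maxi == expected) return(0)
  (a - expected) / (maxi - expected)
}

# random genotype table over `sites` with given loci and allele range
random_genotype_table <- function(n_per_site = 8, sites = c("A", "B"),
                                  loci = 3, alleles = seq(100, 112, by = 2),
                                  missing = 0, seed = 1) {
  set.seed(seed)
  n <- n_per_site * length(sites)
  arr <- array(sample(alleles, n * loci * 2, replace = TRUE), c(n, loci, 2))
  if (missing > 0) arr[runif(length(arr)) < missing] <- NA
  genotype_table(arr, rep(sites, each = n_per_site),
                 repeat_units = rep(2, loci))
}

random_haploset <- function(n = 10, L = 20, n_hap = 4, site = "A",
                            seed = 1) {
  set.seed(seed)
  pool <- replicate(n_hap, paste(sample(c("A", "C", "G", "T"), L,
                                        replace = TRUE), collapse = ""))
  haplotype_set(sample(pool, n, replace = TRUE), site = site)
}
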