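# Diversity and differentiation statistics against brute-force oracles.

test_that("haplotype diversity matches Nei's unbiased estimator", {
  expect_equal(haplotype_diversity(haplotype_set(c("AA", "AA", "AT",
                                                   "AT")))$value,
               2 / 3, tolerance = 1e-12)
  expect_equal(haplotype_diversity(haplotype_set(rep("ACGT", 6)))$value, 0)
  expect_equal(haplotype_diversity(
    haplotype_set(c("AAAA", "AAAT", "AATT", "ATTT", "TTTT")))$value, 1)
  expect_error(haplotype_diversity(haplotype_set("AA")), "n >= 2")

  for (seed in 1:20) {
    hs <- random_haploset(n = sample(4:20, 1), seed = seed)
    expect_equal(haplotype_diversity(hs)$value, oracle_h(hs$sequences),
                 tolerance = 1e-10)
  }
})

test_that("nucleotide diversity averages pairwise site differences", {
  two <- haplotype_set(c("AAAAAAAAAA", "AAAAAAAAAT"))
  expect_equal(nucleotide_diversity(two)$value, 0.1, tolerance = 1e-12)
  expect_equal(nucleotide_diversity(haplotype_set(rep("ACGTAC", 4)))$value, 0)
  tri <- haplotype_set(c("AAAAAAAAAA", "AAAAAAAAAT", "AAAAAAAATT"))
  expect_equal(nucleotide_diversity(tri)$value, (0.1 + 0.2 + 0.1) / 3,
               tolerance = 1e-12)

  # gaps and Ns are pairwise-deleted
  gap <- haplotype_set(c("AAAN-AAAAA", "AAAACAAAAT"))
  expect_equal(nucleotide_diversity(gap)$value, 1 / 8, tolerance = 1e-12)

  for (seed in 1:20) {
    hs <- random_haploset(n = sample(4:20, 1), seed = seed + 100)
    expect_equal(nucleotide_diversity(hs)$value, oracle_pi(hs$sequences),
                 tolerance = 1e-10)
  }
})

test_that("Phi_PT reproduces a hand-computed AMOVA and its permutation p", {
  a <- haplotype_set(rep("AAAA", 8), site = "A")
  b <- haplotype_set(rep("TTTT", 8), site = "B")
  fixed <- phi_pt(list(a, b), permutations = 99, seed = 1)
  expect_equal(fixed$value["A", "B"], 1)
  expect_equal(fixed$p["A", "B"], 1 / 100)

  same <- phi_pt(list(haplotype_set(c("AAAA", "AATT", "AAAA"), site = "A"),
                      haplotype_set(c("AAAA", "AATT", "AAAA"), site = "B")),
                 permutations = 99, seed = 1)
  expect_lte(same$value["A", "B"], 0)

  for (seed in 1:10) {
    s1 <- random_haploset(n = 8, seed = seed, site = "A")
    s2 <- random_haploset(n = 11, seed = seed + 50, site = "B")
    got <- phi_pt(list(s1, s2), permutations = 0, seed = 1)
    expect_equal(got$value["A", "B"],
                 oracle_phi(s1$sequences, s2$sequences), tolerance = 1e-10)
  }

  # symmetric under swapping the two populations
  s1 <- random_haploset(n = 9, seed = 7, site = "A")
  s2 <- random_haploset(n = 6, seed = 8, site = "B")
  expect_equal(phi_pt(list(s1, s2), permutations = 0)$value["A", "B"],
               phi_pt(list(s2, s1), permutations = 0)$value["B", "A"],
               tolerance = 1e-12)

  tiny <- haplotype_set("AAAA", site = "C")
  expect_warning(phi_pt(list(s1, s2, tiny), permutations = 0), "dropping")
})

test_that("F_ST and G''_ST match direct H_S/H_T computation", {
  al <- array(NA_integer_, c(10, 1, 2))
  al[1:5, 1, ] <- 100L
  al[6:10, 1, ] <- 104L
  gt <- genotype_table(al, rep(c("A", "B"), each = 5), repeat_units = 2)
  expect_equal(fst_microsat(gt, permutations = 0)$value["A", "B"], 1)
  expect_equal(g_double_prime_st(gt, permutations = 0)$value["A", "B"], 1)

  # identical allele frequencies imply zero differentiation
  al2 <- array(rep(c(100L, 104L), each = 10), c(10, 1, 2))
  gt2 <- genotype_table(al2, rep(c("A", "B"), each = 5), repeat_units = 2)
  expect_equal(fst_microsat(gt2, permutations = 0)$value["A", "B"], 0,
               tolerance = 1e-12)
  expect_equal(g_double_prime_st(gt2, permutations = 0)$value["A", "B"], 0,
               tolerance = 1e-12)

  # monomorphic pair: value 0 with an explanatory note
  mono <- genotype_table(array(100L, c(6, 1, 2)), rep(c("A", "B"), each = 3),
                         repeat_units = 2)
  fmono <- fst_microsat(mono, permutations = 0)
  expect_equal(fmono$value["A", "B"], 0)
  expect_match(fmono$note, "monomorphic")

  for (seed in 1:50) {
    gt <- random_genotype_table(n_per_site = sample(4:10, 1),
                                loci = sample(2:4, 1),
                                missing = 0.05, seed = seed)
    f <- fst_microsat(gt, permutations = 0)$value["A", "B"]
    g <- g_double_prime_st(gt, permutations = 0)$value["A", "B"]
    expect_equal(f, oracle_fst(gt, "A", "B"), tolerance = 1e-10)
    expect_equal(g, oracle_gppst(gt, "A", "B"), tolerance = 1e-10)
    expect_gte(g, f - 1e-12)             # standardisation never shrinks it
  }
})

test_that("G''_ST is 1 whenever populations share no alleles", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 6
    loci <- 3
    arr <- array(NA_integer_, c(2 * n, loci, 2))
    arr[1:n, , ] <- sample(seq(100, 110, 2), n * loci * 2, replace = TRUE)
    arr[(n + 1):(2 * n), , ] <- sample(seq(130, 140, 2), n * loci * 2,
                                       replace = TRUE)
    gt <- genotype_table(arr, rep(c("A", "B"), each = n),
                         repeat_units = rep(2, loci))
    expect_equal(g_double_prime_st(gt, permutations = 0)$value["A", "B"], 1,
                 tolerance = 1e-10)
  }
})

test_that("allelic richness rarefies by dropping the most-missing individuals", {
  mono <- genotype_table(array(100L, c(4, 1, 2)), rep("A", 4),
                         repeat_units = 2)
  expect_equal(allelic_richness(mono, standard_n = 4, bootstraps = 20,
                                seed = 1)$value, 1)

  al <- array(NA_integer_, c(2, 1, 2))
  al[1, 1, ] <- c(100L, 102L)
  al[2, 1, ] <- c(104L, 106L)
  four <- genotype_table(al, rep("A", 2), repeat_units = 2)
  expect_equal(allelic_richness(four, standard_n = 2, bootstraps = 20,
                                seed = 1)$value, 4)

  # standardisation keeps the least-missing individuals
  al2 <- array(100L, c(4, 2, 2))
  al2[1, , ] <- NA
  al2[2, 1, 1] <- NA
  al2[3, 2, ] <- c(120L, 122L)
  al2[4, 2, ] <- c(124L, 126L)
  gt2 <- genotype_table(al2, rep("A", 4), repeat_units = c(2, 2))
  ar <- allelic_richness(gt2, standard_n = 2, bootstraps = 20, seed = 1)
  expect_equal(ar$value, mean(c(1, 4)))  # individuals 3 and 4 kept

  # subsampling never increases richness on nested data
  gt3 <- random_genotype_table(n_per_site = 10, sites = "A", loci = 4,
                               seed = 9)
  ar10 <- allelic_richness(gt3, standard_n = 10, bootstraps = 10,
                           seed = 1)$value
  gt3_sub <- genotype_table(gt3$alleles[1:5, , , drop = FALSE],
                            gt3$site[1:5], gt3$loci, gt3$repeat_units)
  ar5 <- allelic_richness(gt3_sub, standard_n = 5,
                          bootstraps = 10, seed = 1)$value
  expect_gte(ar10, ar5)
  expect_error(allelic_richness(gt3, standard_n = 1), ">= 2")
  expect_error(allelic_richness(gt3, standard_n = 50), "exceeds")

  # CI brackets the point estimate
  gt4 <- random_genotype_table(n_per_site = 15, sites = c("A", "B"),
                               loci = 5, missing = 0.03, seed = 4)
  ar4 <- allelic_richness(gt4, bootstraps = 200, seed = 2)
  expect_true(all(ar4$ci_lo <= ar4$value + 1e-9))
  expect_true(all(ar4$value <= ar4$ci_hi + 1e-9))
  expect_equal(ar4$value, sapply(c("A", "B"), function(s) {
    oracle_ar(gt4, s)
  }, USE.NAMES = FALSE), tolerance = 1e-10)
})

test_that("diversity-difference permutation test behaves at the extremes", {
  a <- haplotype_set(rep("AAAA", 20), site = "A")
  pool <- c("AAAT", "AATT", "ATTT", "TTTT", "TAAA", "TTAA", "TTTA", "ATAT",
            "TATA", "ACAA", "AACA", "CAAA", "AAAC", "GAAA", "AGAA", "AAGA",
            "AAAG", "CCAA", "AACC", "CACA")
  b <- haplotype_set(pool, site = "B")
  dt <- diversity_diff_test(a, b, iterations = 199, seed = 1)
  expect_equal(dt$p_h, 1 / 200)          # no permutation can reach delta h = 1
  expect_equal(dt$delta_h, 1)

  ident <- diversity_diff_test(a, a, iterations = 99, seed = 1)
  expect_equal(ident$p_h, 1)
  expect_equal(ident$p_pi, 1)
})

test_that("statistics are invariant to relabelling individuals", {
  hs <- random_haploset(n = 12, seed = 3)
  shuf <- haplotype_set(sample(hs$sequences), site = hs$site)
  expect_equal(haplotype_diversity(hs)$value,
               haplotype_diversity(shuf)$value, tolerance = 1e-12)
  expect_equal(nucleotide_diversity(hs)$value,
               nucleotide_diversity(shuf)$value, tolerance = 1e-12)

  gt <- random_genotype_table(n_per_site = 8, seed = 5)
  perm <- sample(dim(gt$alleles)[1])
  gtp <- genotype_table(gt$alleles[perm, , , drop = FALSE], gt$site[perm],
                        gt$loci, gt$repeat_units)
  expect_equal(fst_microsat(gt, permutations = 0)$value,
               fst_microsat(gtp, permutations = 0)$value, tolerance = 1e-12)
})

test_that("Bonferroni correction is min(1, m p)", {
  expect_equal(bonferroni(0.01, m = 10), 0.1)
  expect_equal(bonferroni(0.5, m = 10), 1)
  expect_equal(bonferroni(c(0.2, 0.04), m = 2), c(0.4, 0.08))
  expect_equal(bonferroni(0.3, m = 1), 0.3)
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "at least")
})

test_that("Bruvo distances follow the stepwise-mutation geometry", {
  al <- array(NA_integer_, c(4, 2, 2))
  al[1, , ] <- c(100L, 110L, 100L, 110L)   # locus values per (locus, slot)
  al[1, 1, ] <- c(100L, 100L)
  al[1, 2, ] <- c(110L, 110L)
  al[2, 1, ] <- c(100L, 100L)
  al[2, 2, ] <- c(110L, 110L)
  al[3, 1, ] <- c(102L, 102L)
  al[3, 2, ] <- c(110L, 110L)
  al[4, 1, ] <- c(104L, 104L)
  al[4, 2, ] <- c(110L, 110L)
  gt <- genotype_table(al, rep("A", 4), repeat_units = c(2, 2))
  D <- bruvo_distance(gt)
  expect_equal(D[1, 2], 0)                       # identical genotypes
  expect_equal(D[1, 3], (1 - 2^-1) / 2)          # one locus, 1 repeat apart
  expect_equal(D[1, 4], (1 - 2^-2) / 2)          # one locus, 2 repeats apart

  # min-weight pairing against explicit enumeration on random genotypes
  set.seed(21)
  for (k in 1:25) {
    g1 <- sample(5:15, 2)
    g2 <- sample(5:15, 2)
    got <- achconnect:::bruvo_locus(g1, g2)
    expect_equal(got, oracle_bruvo_geno(g1, g2), tolerance = 1e-12)
  }
  expect_error(bruvo_distance(genotype_table(al, rep("A", 4),
                                             repeat_units = c(0, 2))))
})

test_that("the minimum spanning network spans and keeps tied edges", {
  set.seed(13)
  pts <- matrix(rnorm(14), 7, 2)
  D <- as.matrix(dist(pts))
  edges <- minimum_spanning_network(D)
  # connects everything with at least n - 1 edges
  expect_gte(nrow(edges), 6)
  g <- unique(c(edges$from, edges$to))
  expect_setequal(g, rownames(D))
  # total weight of a spanning subset equals ape's MST weight
  mst <- ape::mst(D)
  w_ape <- sum(D[which(mst == 1 & upper.tri(mst))])
  base_edges <- edges[!duplicated(paste(edges$from, edges$to)), ]
  expect_equal(sum(sort(base_edges$weight)[1:6]), w_ape, tolerance = 1e-9)

  # tied alternatives are all retained
  Dt <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3)
  et <- minimum_spanning_network(Dt)
  expect_equal(nrow(et), 3)
})
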