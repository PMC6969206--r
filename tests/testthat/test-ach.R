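# Cover summaries, lineage partitioning and the centre-edge verdict.

cover_fixture <- function() {
  path <- system.file("extdata", "cover_table.csv", package = "achconnect")
  utils::read.csv(path)
}

test_that("group cover means average site means with equal weights", {
  tab <- cover_fixture()
  rec <- data.frame(site = tab$site, cover = tab$cover,
                    lineage = tab$lineage, category = tab$category)
  out <- summarize_cover(rec)
  pick <- function(lin, cat) out$mean_2dp[out$lineage == lin &
                                            out$category == cat]
  expect_equal(pick("west", "edge"), 0.13)
  expect_equal(pick("west", "centre"), 58.47)
  expect_equal(pick("east", "centre"), 72.59)

  # invariant to quadrat ordering; singleton group equals the site mean
  quad <- data.frame(site = rep(c("S1", "S2"), each = 3),
                     cover = c(10, 20, 30, 5, 5, 5),
                     lineage = "west",
                     category = c(rep("centre", 3), rep("edge", 3)))
  o1 <- summarize_cover(quad)
  o2 <- summarize_cover(quad[sample(nrow(quad)), ])
  expect_equal(o1, o2)
  expect_equal(o1$mean[o1$category == "edge"], 5)
  expect_equal(o1$mean[o1$category == "centre"], 20)
  bad <- quad
  bad$cover[1] <- 130
  expect_error(summarize_cover(bad), "0, 100")
})

test_that("lineage partitioning conserves the total and matches print rules", {
  p5 <- partition_cover_by_lineage(66.2, 0.50)
  expect_equal(unname(p5["western"]), 33.1)
  expect_equal(unname(p5["eastern"]), 33.1)

  p6 <- partition_cover_by_lineage(52.1, 0.30)
  expect_equal(unname(p6["western"]), 15.63)
  expect_equal(unname(p6["eastern"]), 36.47)
  expect_equal(round_down1(p6["western"]), c(western = 15.6))
  expect_equal(round_down1(p6["eastern"]), c(eastern = 36.4))

  zero <- partition_cover_by_lineage(40, 0)
  expect_equal(unname(zero), c(0, 40))
  for (tot in c(0, 17.3, 66.2, 100)) {
    for (f in c(0, 0.25, 0.5, 0.9, 1)) {
      parts <- partition_cover_by_lineage(tot, f)
      expect_equal(sum(parts), tot, tolerance = 1e-12)
    }
  }
  expect_error(partition_cover_by_lineage(50, 1.2), "0, 1")
})

test_that("the verdict requires significantly lower edge diversity", {
  sites <- data.frame(code = c("C1", "C2", "E1", "E2"),
                      lineage = "west",
                      category = c("centre", "centre", "edge", "edge"))
  # clearly separated CIs: supported (no differentiation matrix supplied)
  div_low <- data.frame(site = sites$code, statistic = "A_r",
                        value = c(10, 11, 5, 6), sd = 0.3,
                        ci_lo = c(9.4, 10.4, 4.4, 5.4),
                        ci_hi = c(10.6, 11.6, 5.6, 6.6), n = 40)
  v <- evaluate_ach(div_low, sites)
  expect_equal(v$table$conclusion, "supported")
  expect_equal(v$table$n_edge_low, 2)

  # all CIs overlapping: no significant differences, rejected
  div_flat <- div_low
  div_flat$value <- c(10, 11, 9.8, 10.5)
  div_flat$ci_lo <- div_flat$value - 2
  div_flat$ci_hi <- div_flat$value + 2
  vf <- evaluate_ach(div_flat, sites)
  expect_equal(vf$table$conclusion, "rejected")
  expect_equal(vf$table$n_edge_low, 0)

  # lineage without edge sites is skipped with a note
  sites2 <- data.frame(code = c("C1", "C2"), lineage = "east",
                       category = "centre")
  div2 <- data.frame(site = sites2$code, statistic = "A_r",
                     value = c(10, 11), sd = 0.3, ci_lo = c(9, 10),
                     ci_hi = c(11, 12), n = 40)
  v2 <- evaluate_ach(div2, sites2)
  expect_match(v2$table$conclusion, "skipped")
})

test_that("the verdict also demands elevated edge divergence when supplied", {
  sites <- data.frame(code = c("C1", "C2", "E1", "E2"),
                      lineage = "west",
                      category = c("centre", "centre", "edge", "edge"))
  div_low <- data.frame(site = sites$code, statistic = "A_r",
                        value = c(10, 11, 5, 6), sd = 0.3,
                        ci_lo = c(9.4, 10.4, 4.4, 5.4),
                        ci_hi = c(10.6, 11.6, 5.6, 6.6), n = 40)
  mk_diff <- function(vals) {
    m <- matrix(0, 4, 4, dimnames = list(sites$code, sites$code))
    m[upper.tri(m)] <- vals
    m <- m + t(m)
    structure(list(statistic = "F_ST", sites = sites$code, value = m,
                   p = m * NA, p_adj = m * NA, permutations = 0),
              class = "diff_matrix")
  }
  # edge pairs more divergent than the centre-centre pair: supported
  hi_edge <- mk_diff(c(0.01, 0.10, 0.12, 0.11, 0.13, 0.09))
  expect_equal(evaluate_ach(div_low, sites,
                            diff = hi_edge)$table$conclusion, "supported")
  # centre-centre divergence dominates: rejected despite low edge diversity
  lo_edge <- mk_diff(c(0.30, 0.02, 0.01, 0.02, 0.01, 0.02))
  expect_equal(evaluate_ach(div_low, sites,
                            diff = lo_edge)$table$conclusion, "rejected")
})

test_that("clustering agreement reproduces the adjusted Rand index", {
  g <- c(A = "x", B = "x", C = "y", D = "y")
  identical_cl <- c(A = 1, B = 1, C = 2, D = 2)
  expect_equal(compare_clusterings(g, identical_cl)$ari, 1)

  allone <- c(A = 1, B = 1, C = 1, D = 1)
  expect_equal(compare_clusterings(g, allone)$ari, 0)

  set.seed(2)
  sites <- paste0("s", 1:12)
  for (k in 1:10) {
    g <- stats::setNames(sample(c("w", "c", "e"), 12, replace = TRUE), sites)
    m <- stats::setNames(sample(1:3, 12, replace = TRUE), sites)
    expect_equal(compare_clusterings(g, m)$ari, oracle_ari(g[sites], m[sites]),
                 tolerance = 1e-10)
  }
  expect_error(compare_clusterings(g, c(bad = 1)), "same site set")
})
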