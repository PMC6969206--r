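# Bruvo's stepwise-mutation distance between diploid microsatellite
# genotypes, and a minimum spanning network over individuals.

# distance between two single alleles, in repeat units
bruvo_allele <- function(x, y) 1 - 2^(-abs(x - y))

# distance between two complete diploid genotypes (repeat units):
# minimum-weight matching of the two allele pairs
bruvo_genotype <- function(a, b) {
  min((bruvo_allele(a[1], b[1]) + bruvo_allele(a[2], b[2])) / 2,
      (bruvo_allele(a[1], b[2]) + bruvo_allele(a[2], b[1])) / 2)
}

# one-locus distance with the average addition/loss model for a single
# missing allele: the missing slot is imputed with the individual's own
# remaining allele (genome loss) and with each allele of the other genotype
# (genome addition), and the genotype distance is averaged over imputations.
bruvo_locus <- function(a, b) {
  na_a <- is.na(a)
  na_b <- is.na(b)
  if (sum(na_a) == 2 || sum(na_b) == 2) return(NA_real_)
  if (!any(na_a) && !any(na_b)) return(bruvo_genotype(a, b))
  impute <- function(g, other) {
    known <- g[!is.na(g)]
    lapply(c(known, other), function(x) c(known, x))
  }
  gas <- if (any(na_a)) impute(a, b[!na_b]) else list(a)
  gbs <- if (any(na_b)) impute(b, a[!na_a]) else list(b)
  mean(vapply(gas, function(ga) {
    mean(vapply(gbs, function(gb) bruvo_genotype(ga, gb), numeric(1)))
  }, numeric(1)))
}

#' Bruvo distances between individuals
#'
#' Microsatellite distance designed for stepwise mutation: two alleles `x`
#' and `y` repeat units apart are at distance \eqn{1 - 2^{-|x - y|}}.
#' Diploid genotypes are compared by minimum-weight matching of their allele
#' pairs; allele sizes are converted to repeat units with each locus's
#' repeat unit length. A genotype with one missing allele is handled by the
#' average addition/loss model (averaging over imputations from the
#' individual's own remaining allele and the other genotype's alleles);
#' loci missing entirely in either individual are dropped from the
#' across-locus average.
#'
#' @param gt a [genotype_table()] with known repeat units.
#' @return symmetric matrix of mean across-locus distances in `[0, 1]`.
#' @export
bruvo_distance <- function(gt) {
  stopifnot(inherits(gt, "genotype_table"))
  if (any(gt$repeat_units <= 0)) fail("repeat units must be positive")
  n <- dim(gt$alleles)[1]
  nl <- dim(gt$alleles)[2]
  # convert to repeat units once
  ru <- array(rep(gt$repeat_units, each = n), dim(gt$alleles))
  A <- gt$alleles / ru
  D <- matrix(0, n, n)
  for (i in seq_len(max(n - 1, 0))) {
    for (j in (i + 1):n) {
      d <- vapply(seq_len(nl), function(l) {
        bruvo_locus(A[i, l, ], A[j, l, ])
      }, numeric(1))
      D[i, j] <- D[j, i] <- mean(d, na.rm = TRUE)
    }
  }
  dimnames(D) <- list(seq_len(n), seq_len(n))
  D
}

#' Minimum spanning network over a distance matrix
#'
#' Kruskal's minimum spanning tree in which all edges tied (to within
#' `tol`) with an accepted edge between the same pair of components are
#' retained, turning the tree into a network. Edge acceptance at a given
#' weight level is decided against the components as they stood before that
#' level, so tied alternatives are kept symmetrically.
#'
#' @param D symmetric distance matrix.
#' @param ids node labels (default from `D`'s dimnames).
#' @param tol tie tolerance on edge weights.
#' @return data frame of network edges: `from`, `to`, `weight`.
#' @export
minimum_spanning_network <- function(D, ids = NULL, tol = 1e-9) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (is.null(ids)) ids <- rownames(D) %||% as.character(seq_len(n))
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  ut <- which(upper.tri(D), arr.ind = TRUE)
  w <- D[ut]
  ord <- order(w, ut[, 1], ut[, 2])
  ut <- ut[ord, , drop = FALSE]
  w <- w[ord]
  edges <- NULL
  i <- 1
  while (i <= length(w)) {
    lvl <- which(abs(w - w[i]) <= tol & seq_along(w) >= i)
    # component state before this weight level
    comp_before <- vapply(seq_len(n), find, integer(1))
    accept <- logical(length(lvl))
    for (e in seq_along(lvl)) {
      a <- ut[lvl[e], 1]
      b <- ut[lvl[e], 2]
      accept[e] <- comp_before[a] != comp_before[b]
    }
    for (e in which(accept)) {
      a <- find(ut[lvl[e], 1])
      b <- find(ut[lvl[e], 2])
      if (a != b) parent[a] <- b
      edges <- rbind(edges, data.frame(from = ids[ut[lvl[e], 1]],
                                       to = ids[ut[lvl[e], 2]],
                                       weight = w[lvl[e]]))
    }
    i <- max(lvl) + 1
  }
  if (is.null(edges)) edges <- data.frame(from = character(0),
                                          to = character(0),
                                          weight = numeric(0))
  rownames(edges) <- NULL
  edges
}
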