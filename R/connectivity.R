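# Connectivity matrices from trajectories, stepping-stone path probabilities
# via Floyd-Warshall on -log probabilities, and modularity clustering.

#' Build a connectivity matrix from trajectories
#'
#' The probability of connection P(i -> j) is the number of particles
#' released at coastal point i that settled at point j, divided by the total
#' number released at i. Lost particles contribute to no destination, so row
#' sums are at most 1 and the shortfall is the lost fraction.
#'
#' @param ts a [trajectory_set][run_release].
#' @return a `connectivity_matrix`: probability matrix `P` (origins in rows),
#'   `released` per-origin totals, `arrivals` per-pair counts, and a label.
#' @export
build_matrix <- function(ts) {
  stopifnot(inherits(ts, "trajectory_set"))
  ids <- ts$point_ids
  released <- ts$released
  if (any(released == 0)) {
    warning("origins with zero releases excluded: ",
            paste(ids[released == 0], collapse = ", "))
    keep <- released > 0
    ids <- ids[keep]
    released <- released[keep]
  }
  p <- ts$particles
  s <- p[p$fate == "settled" & p$origin_id %in% ids, ]
  arrivals <- table(factor(s$origin_id, levels = ids),
                    factor(s$settle_id, levels = ids))
  arrivals <- matrix(as.integer(arrivals), length(ids), length(ids),
                     dimnames = list(ids, ids))
  P <- arrivals / released
  structure(list(point_ids = ids, P = P, released = released,
                 arrivals = arrivals, label = as.character(ts$year)),
            class = "connectivity_matrix")
}

#' Average annual connectivity matrices
#'
#' Elementwise arithmetic mean of per-year probability matrices, accounting
#' for inter-annual variability in the flow.
#'
#' @param yearly list of [connectivity_matrix][build_matrix] objects over the
#'   same point set.
#' @return a `connectivity_matrix` labelled `"averaged"`.
#' @export
average_matrices <- function(yearly) {
  stopifnot(length(yearly) >= 1)
  ids <- yearly[[1]]$point_ids
  for (m in yearly) {
    stopifnot(inherits(m, "connectivity_matrix"))
    if (!identical(m$point_ids, ids)) fail("mismatched point sets")
  }
  P <- Reduce(`+`, lapply(yearly, `[[`, "P")) / length(yearly)
  structure(list(point_ids = ids, P = P,
                 released = Reduce(`+`, lapply(yearly, `[[`, "released")),
                 arrivals = Reduce(`+`, lapply(yearly, `[[`, "arrivals")),
                 label = "averaged"),
            class = "connectivity_matrix")
}

# Floyd-Warshall on w = -log P with next-hop tracking. Zero probabilities are
# absent edges (infinite weight), never an epsilon. Relaxation is strict
# improvement under a fixed scan order, so output is deterministic.
floyd_warshall_maxprod <- function(P) {
  n <- nrow(P)
  W <- -log(P)
  W[P <= 0] <- Inf
  diag(W) <- 0
  nxt <- matrix(rep(seq_len(n), each = n), n, n)
  nxt[!is.finite(W)] <- NA_integer_
  diag(nxt) <- seq_len(n)
  for (k in seq_len(n)) {
    if (all(!is.finite(W[, k]))) next
    cand <- outer(W[, k], W[k, ], `+`)
    upd <- cand < W - 1e-15
    if (any(upd)) {
      W[upd] <- cand[upd]
      nxt[upd] <- nxt[row(upd)[upd], k]
    }
  }
  list(W = W, nxt = nxt)
}

fw_path <- function(nxt, i, j) {
  if (is.na(nxt[i, j])) return(integer(0))
  path <- i
  while (i != j) {
    i <- nxt[i, j]
    path <- c(path, i)
    if (length(path) > nrow(nxt) + 1) return(integer(0))  # defensive
  }
  path
}

#' Stepping-stone connection probabilities between sampled locations
#'
#' Multi-generation connectivity allows larvae to use intermediate coastal
#' points: the stepping-stone probability between two locations is the
#' maximum over paths of the product of single-step probabilities. It is
#' found as the shortest path on edge weights \eqn{-\log P(i \to j)}
#' (Floyd-Warshall), with the probability recovered as \eqn{\exp(-L)} for
#' path length \eqn{L}. All coastal points are graph vertices; the sampled
#' locations are only the query endpoints.
#'
#' @param cm a [connectivity_matrix][build_matrix].
#' @param sampled_ids point ids of the sampled locations (default: all).
#' @return a `stepping_stone_result`: matrices `prob` (max-product path
#'   probability) and `direct` (single-step probability) over the sampled
#'   ids, and `paths`, a list of ordered point-id vectors per ordered pair.
#' @export
stepping_stone <- function(cm, sampled_ids = cm$point_ids) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  if (any(cm$P < 0 | cm$P > 1)) fail("probabilities must lie in [0, 1]")
  idx <- match(sampled_ids, cm$point_ids)
  if (anyNA(idx)) fail("sampled_ids not all present in the matrix")
  fw <- floyd_warshall_maxprod(cm$P)
  k <- length(idx)
  prob <- matrix(0, k, k, dimnames = list(sampled_ids, sampled_ids))
  direct <- cm$P[idx, idx, drop = FALSE]
  dimnames(direct) <- dimnames(prob)
  paths <- vector("list", k * k)
  dim(paths) <- c(k, k)
  dimnames(paths) <- dimnames(prob)
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      i <- idx[a]; j <- idx[b]
      if (a == b) { prob[a, b] <- 1; paths[[a, b]] <- cm$point_ids[i]; next }
      w <- fw$W[i, j]
      if (is.finite(w)) {
        prob[a, b] <- exp(-w)
        paths[[a, b]] <- cm$point_ids[fw_path(fw$nxt, i, j)]
      } else {
        paths[[a, b]] <- integer(0)
      }
    }
  }
  structure(list(sampled_ids = sampled_ids, prob = prob, direct = direct,
                 paths = paths),
            class = "stepping_stone_result")
}

#' Directed weighted modularity of a partition
#'
#' Newman modularity for a directed weighted graph:
#' \deqn{Q = \frac{1}{m} \sum_{i \ne j} \left[A_{ij} -
#'   \frac{k_i^{out} k_j^{in}}{m}\right] \delta(c_i, c_j)}
#' with \eqn{m} the total off-diagonal edge weight. Self-loops (larval
#' retention) are excluded.
#'
#' @param A weighted adjacency matrix (edge weights = probabilities).
#' @param membership integer cluster label per node.
#' @return modularity value Q.
#' @export
directed_modularity <- function(A, membership) {
  A <- as.matrix(A)
  diag(A) <- 0
  m <- sum(A)
  if (m <= 0) return(0)
  kout <- rowSums(A)
  kin <- colSums(A)
  # self-loop edges are excluded (diag(A) = 0) but the null-model term keeps
  # all ordered pairs, as in the standard directed Newman form
  B <- A / m - outer(kout, kin) / m^2
  same <- outer(membership, membership, `==`)
  sum(B[same])
}

# Enumerate all set partitions of n items as restricted-growth strings in
# lexicographic order (Knuth 7.2.1.5 Algorithm H), applying f to each
# 1-based membership vector. The caller caps n (Bell numbers grow fast).
for_each_partition <- function(n, f) {
  if (n == 1) { f(1L); return(invisible()) }
  a <- integer(n)          # 0-based restricted growth string
  b <- rep(1L, n)          # b[j] = 1 + max(a[1..j-1])
  repeat {
    f(a + 1L)
    if (a[n] < b[n]) { a[n] <- a[n] + 1L; next }
    j <- n - 1L
    while (j > 1L && a[j] == b[j]) j <- j - 1L
    if (j == 1L) break
    a[j] <- a[j] + 1L
    bb <- b[j] + (a[j] == b[j])
    a[(j + 1L):n] <- 0L
    b[(j + 1L):n] <- bb
  }
  invisible()
}

#' Cluster locations by maximising modularity
#'
#' Finds the partition of the sampled locations that maximises directed
#' weighted modularity of the (stepping-stone or direct) connectivity graph.
#' For small location sets every set partition is scored exhaustively; above
#' `exhaustive_max` locations a greedy agglomerative search is used and the
#' result is flagged accordingly.
#'
#' @param cm a [connectivity_matrix][build_matrix], or a square probability
#'   matrix (e.g. the `prob` matrix of [stepping_stone()]).
#' @param sampled_ids locations to cluster (default: all points of `cm`).
#' @param exhaustive_max largest location count for which the exhaustive
#'   Bell-number scan is attempted (default 10).
#' @return a `cluster_partition`: `membership` (named integer vector),
#'   `Q` (modularity of the returned partition), `n_clusters`, and `method`
#'   (`"exhaustive"` or `"greedy"`).
#' @export
cluster_modularity <- function(cm, sampled_ids = NULL, exhaustive_max = 10) {
  if (inherits(cm, "connectivity_matrix")) {
    ids <- if (is.null(sampled_ids)) cm$point_ids else sampled_ids
    idx <- match(ids, cm$point_ids)
    if (anyNA(idx)) fail("sampled_ids not all present in the matrix")
    A <- cm$P[idx, idx, drop = FALSE]
  } else {
    A <- as.matrix(cm)
    if (nrow(A) != ncol(A)) fail("matrix must be square")
    ids <- if (is.null(sampled_ids)) {
      if (!is.null(rownames(A))) rownames(A) else seq_len(nrow(A))
    } else sampled_ids
  }
  n <- nrow(A)
  if (n == 0) fail("empty graph")
  diag(A) <- 0
  if (sum(A) <= 0) fail("graph has no edges")

  if (n <= exhaustive_max) {
    m <- sum(A)
    B <- A / m - outer(rowSums(A), colSums(A)) / m^2
    best_q <- -Inf
    best <- rep(1L, n)
    env <- environment()
    for_each_partition(n, function(memb) {
      same <- outer(memb, memb, `==`)
      q <- sum(B[same])
      # prefer fewer clusters on ties so the uniform graph returns one cluster
      if (q > env$best_q + 1e-12 ||
          (abs(q - env$best_q) <= 1e-12 && max(memb) < max(env$best))) {
        env$best_q <- q
        env$best <- memb
      }
    })
    membership <- best
    Q <- directed_modularity(A, membership)
    method <- "exhaustive"
  } else {
    res <- greedy_modularity(A)
    membership <- res$membership
    Q <- res$Q
    method <- "greedy"
  }
  membership <- stats::setNames(match(membership, unique(membership)), ids)
  structure(list(membership = membership, Q = Q,
                 n_clusters = length(unique(membership)), method = method),
            class = "cluster_partition")
}

# Agglomerative merging: start from singletons, repeatedly merge the cluster
# pair with the largest modularity gain while a positive gain exists.
greedy_modularity <- function(A) {
  n <- nrow(A)
  memb <- seq_len(n)
  q <- directed_modularity(A, memb)
  repeat {
    labs <- unique(memb)
    if (length(labs) == 1) break
    best_gain <- 0
    best_pair <- NULL
    for (a in seq_along(labs)) {
      for (b in seq_along(labs)) {
        if (a >= b) next
        trial <- memb
        trial[trial == labs[b]] <- labs[a]
        gain <- directed_modularity(A, trial) - q
        if (gain > best_gain + 1e-12) {
          best_gain <- gain
          best_pair <- c(labs[a], labs[b])
        }
      }
    }
    if (is.null(best_pair)) break
    memb[memb == best_pair[2]] <- best_pair[1]
    q <- q + best_gain
  }
  list(membership = memb, Q = directed_modularity(A, memb))
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("Connectivity matrix (%s): %d points\n", x$label,
              length(x$point_ids)))
  cat(sprintf("  mean retention %.3f, mean row sum %.3f\n",
              mean(diag(x$P)), mean(rowSums(x$P))))
  invisible(x)
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat(sprintf("Modularity partition (%s): %d clusters, Q = %.4f\n",
              x$method, x$n_clusters, x$Q))
  print(split(names(x$membership), x$membership))
  invisible(x)
}

#' @export
plot.connectivity_matrix <- function(x, log = TRUE, ...) {
  z <- x$P
  if (log) z <- log10(z + 1e-8)
  graphics::image(seq_along(x$point_ids), seq_along(x$point_ids), t(z),
                  xlab = "Destination", ylab = "Origin",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}
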