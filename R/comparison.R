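# Direct graph-to-graph distances and correlations. All of these require
# the two adjacency matrices to match in size.

check_same_n <- function(g1, g2) {
  if (igraph::vcount(g1) != igraph::vcount(g2))
    stopf("the adjacency matrices must match in size (%d vs %d nodes)",
          igraph::vcount(g1), igraph::vcount(g2))
}

#' Hamming distance between two graphs
#'
#' Number of adjacency entries in which the two graphs disagree; the number
#' of edge additions/deletions needed to turn one edge set into the other.
#' In `"ordered"` mode the sum runs over all ordered pairs (each undirected
#' disagreement counts twice); `"unordered"` halves this for undirected
#' graphs.
#'
#' @param g1,g2 unweighted igraph objects on the same number of nodes.
#' @param pair_mode `"ordered"` (default, matches the indicator-sum
#'   formula) or `"unordered"`.
#' @return integer count.
#' @export
hamming_distance <- function(g1, g2, pair_mode = c("ordered", "unordered")) {
  pair_mode <- match.arg(pair_mode)
  check_graph(g1, weighted = FALSE); check_graph(g2, weighted = FALSE)
  check_same_n(g1, g2)
  A1 <- adjacency_of(g1); A2 <- adjacency_of(g2)
  d <- sum(off_diagonal(A1) != off_diagonal(A2))
  if (pair_mode == "unordered" &&
      !igraph::is_directed(g1) && !igraph::is_directed(g2)) d <- d / 2
  as.integer(d)
}

# all n! permutations of 1..n, one per row (n <= 8)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 1L
  for (pos in seq_len(n)) for (s in seq_len(nrow(sub))) {
    row <- integer(n); row[pos] <- n
    row[-pos] <- sub[s, ]
    out[r, ] <- row; r <- r + 1L
  }
  out
}

#' Structural distance (label-invariant Hamming distance)
#'
#' Minimum Hamming distance over relabelings of the second graph -- the
#' distance between graphs when node identities are interchangeable.
#' `method = "exact"` enumerates all `N!` permutations (only for `N <= 8`);
#' `"anneal"` searches by simulated annealing over permutations (2-opt node
#' swaps, geometric cooling) and returns the best value found, flagged
#' approximate; it never exceeds the plain Hamming distance.
#'
#' @inheritParams hamming_distance
#' @param method `"exact"` or `"anneal"`.
#' @param n_proposals annealing proposals (default 1e4).
#' @param seed RNG seed for annealing.
#' @return list with `distance`, `method`, `exact` flag and (for annealing)
#'   the best permutation found.
#' @export
structural_distance <- function(g1, g2, method = c("exact", "anneal"),
                                n_proposals = 1e4, seed = NULL) {
  method <- match.arg(method)
  check_graph(g1, weighted = FALSE); check_graph(g2, weighted = FALSE)
  check_same_n(g1, g2)
  A1 <- adjacency_of(g1); A2 <- adjacency_of(g2)
  n <- nrow(A1)
  offd <- row(A1) != col(A1)
  cost <- function(p) sum(A1[offd] != A2[p, p][offd])
  if (method == "exact") {
    if (n > 8) stopf("exact search is limited to N <= 8; use method='anneal'")
    perms <- all_permutations(n)
    best <- Inf
    for (r in seq_len(nrow(perms))) {
      d <- cost(perms[r, ])
      if (d < best) best <- d
      if (best == 0) break
    }
    return(list(distance = as.integer(best), method = "exact", exact = TRUE))
  }
  with_seed(seed, {
    p <- seq_len(n)
    cur <- cost(p); best <- cur; best_p <- p
    temp <- max(cur, 1); cool <- (0.01 / temp)^(1 / n_proposals)
    for (t in seq_len(n_proposals)) {
      ij <- sample.int(n, 2)
      q <- p; q[ij] <- q[rev(ij)]
      d <- cost(q)
      if (d <= cur || runif(1) < exp((cur - d) / temp)) { p <- q; cur <- d }
      if (cur < best) { best <- cur; best_p <- p }
      temp <- temp * cool
    }
    list(distance = as.integer(best), method = "anneal", exact = FALSE,
         permutation = best_p)
  })
}

#' Graph covariance and correlation, with attainable bounds
#'
#' Treats the off-diagonal adjacency entries of the two graphs as paired
#' observations: the means `m1`, `m2` equal the edge densities for
#' unweighted graphs, and the correlation is +1 only when the edge sets
#' coincide and -1 only when the graphs are exact mirrors. Because the
#' densities are generally unequal, the attainable correlation range is
#' narrower than \[-1, 1\]; the bounds are obtained by reordering the entries
#' for maximal overlap (both sorted descending) and maximal anti-overlap,
#' and the correlation is also reported normalized by its attainable
#' maximum.
#'
#' @param g1,g2 igraph objects on the same number of nodes, neither empty
#'   nor complete (nonzero variance required).
#' @return list with `covariance`, `correlation`, `graph_means`,
#'   `correlation_bounds` (min and max attainable), and
#'   `normalized_correlation` (= correlation / max attainable).
#' @export
graph_correlation <- function(g1, g2) {
  check_graph(g1); check_graph(g2)
  check_same_n(g1, g2)
  a1 <- off_diagonal(adjacency_of(g1))
  a2 <- off_diagonal(adjacency_of(g2))
  m1 <- mean(a1); m2 <- mean(a2)
  v1 <- mean(a1^2) - m1^2; v2 <- mean(a2^2) - m2^2
  if (v1 <= 0) stopf("first graph has zero variance (empty or complete)")
  if (v2 <= 0) stopf("second graph has zero variance (empty or complete)")
  cv <- mean(a1 * a2) - m1 * m2
  rho <- cv / sqrt(v1 * v2)
  pop_cor <- function(x, y) (mean(x * y) - mean(x) * mean(y)) / sqrt(v1 * v2)
  hi <- pop_cor(sort(a1, decreasing = TRUE), sort(a2, decreasing = TRUE))
  lo <- pop_cor(sort(a1, decreasing = TRUE), sort(a2))
  list(covariance = cv, correlation = rho,
       graph_means = c(m1 = m1, m2 = m2),
       correlation_bounds = c(min = lo, max = hi),
       normalized_correlation = rho / hi)
}

#' Coincidence similarity between two graphs
#'
#' Geometric mean of the fraction of the first graph's ones that coincide
#' with ones in the second and the fraction of its off-diagonal zeros that
#' coincide with zeros -- a normalization that corrects the large baseline
#' agreement of sparse binary matrices. Equals 1 only for identical
#' adjacency matrices. Note the measure is asymmetric: ratios are taken
#' with respect to the first graph.
#'
#' @inheritParams hamming_distance
#' @return similarity in \[0, 1\].
#' @export
costa_similarity <- function(g1, g2) {
  check_graph(g1, weighted = FALSE); check_graph(g2, weighted = FALSE)
  check_same_n(g1, g2)
  a1 <- off_diagonal(adjacency_of(g1))
  a2 <- off_diagonal(adjacency_of(g2))
  n1 <- sum(a1 == 1); n0 <- sum(a1 == 0)
  if (n1 == 0 || n0 == 0)
    stopf("similarity undefined: first graph is empty or complete")
  r_ones <- sum(a1 == 1 & a2 == 1) / n1
  r_zeros <- sum(a1 == 0 & a2 == 0) / n0
  sqrt(r_ones * r_zeros)
}

#' All pairwise comparison measures at once
#'
#' @inheritParams hamming_distance
#' @param structural_method passed to [structural_distance()]; `NULL` skips
#'   the (potentially expensive) structural distance.
#' @param seed RNG seed for annealing.
#' @return list combining [hamming_distance()], [structural_distance()],
#'   [graph_correlation()] and [costa_similarity()] results.
#' @export
compare_graphs <- function(g1, g2, structural_method = NULL, seed = NULL) {
  out <- list(hamming = hamming_distance(g1, g2))
  if (!is.null(structural_method))
    out$structural <- structural_distance(g1, g2, structural_method,
                                          seed = seed)
  out <- c(out, graph_correlation(g1, g2))
  out$costa_similarity <- costa_similarity(g1, g2)
  out
}
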