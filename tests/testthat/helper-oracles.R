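# Independent brute-force oracles, deliberately written against plain
# adjacency matrices (no igraph, no package internals) so they can serve as
# references for the implementation.

# breadth-first-search distances from every node; Inf where unreachable
bfs_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(A[v, ] > 0)
        new <- nb[dist[nb] == Inf]
        dist[new] <- dist[v] + 1
        nxt <- c(nxt, new)
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
  }
  D
}

oracle_path_length <- function(A) {
  D <- bfs_distances(A)
  d <- D[row(D) != col(D)]
  list(L = mean(d[is.finite(d)]), frac = mean(is.finite(d)))
}

# per-node triangle enumeration
oracle_clustering <- function(A) {
  n <- nrow(A)
  ci <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] > 0)
    k <- length(nb)
    if (k < 2) { ci[v] <- 0; next }
    links <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      if (A[nb[a], nb[b]] > 0) links <- links + 1
    ci[v] <- links / (k * (k - 1) / 2)
  }
  mean(ci)
}

# exhaustive-permutation structural distance (recursive permutation
# generation, independent of the package's enumerator)
oracle_structural_distance <- function(A1, A2) {
  n <- nrow(A1)
  offd <- row(A1) != col(A1)
  best <- Inf
  rec <- function(perm, rest) {
    if (!length(rest)) {
      d <- sum(A1[offd] != A2[perm, perm][offd])
      if (d < best) best <<- d
      return()
    }
    for (x in rest) rec(c(perm, x), setdiff(rest, x))
  }
  rec(integer(0), seq_len(n))
  best
}

# classify one labelled 3-node digraph into a Davis-Leinhardt label by
# counting dyads and matching degree fingerprints
rand_digraph <- function(n, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rbinom(n * n, 1, p), n, n)
  diag(A) <- 0L
  igraph::graph_from_adjacency_matrix(A, mode = "directed")
}

rand_graph <- function(n, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, p)
  A <- A + t(A)
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

adj_of <- function(g) as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))

expect_close <- function(x, y, tol) expect_lt(abs(x - y), tol)
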