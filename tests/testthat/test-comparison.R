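test_that("Hamming distance counts disagreements in both pair modes", {
  g <- rand_graph(6, 0.5, seed = 61)
  expect_equal(hamming_distance(g, g), 0)
  # remove one edge: both orientations disagree in ordered mode
  g2 <- igraph::delete_edges(g, 1)
  expect_equal(hamming_distance(g, g2, "ordered"), 2)
  expect_equal(hamming_distance(g, g2, "unordered"), 1)
  empty <- igraph::make_empty_graph(4, directed = FALSE)
  full <- igraph::make_full_graph(4)
  expect_equal(hamming_distance(empty, full, "ordered"), 12)
  expect_error(hamming_distance(g, rand_graph(7, 0.5)), "match in size")
})

test_that("Hamming distance satisfies the metric axioms", {
  set.seed(62)
  for (r in 1:50) {
    n <- sample(4:7, 1)
    a <- rand_graph(n, runif(1, 0.2, 0.8))
    b <- rand_graph(n, runif(1, 0.2, 0.8))
    c <- rand_graph(n, runif(1, 0.2, 0.8))
    dab <- hamming_distance(a, b); dba <- hamming_distance(b, a)
    expect_equal(dab, dba)
    expect_equal(hamming_distance(a, a), 0)
    expect_lte(hamming_distance(a, c), dab + hamming_distance(b, c))
    if (dab == 0)
      expect_equal(adj_of(a), adj_of(b))
  }
})

test_that("exact structural distance matches the exhaustive oracle", {
  # relabeled copy has distance 0
  set.seed(63)
  g <- rand_graph(6, 0.5)
  perm <- sample(6)
  A <- adj_of(g)
  g_perm <- igraph::graph_from_adjacency_matrix(A[perm, perm],
                                                mode = "undirected")
  expect_equal(structural_distance(g, g_perm, "exact")$distance, 0)

  # path vs star on 4 nodes, against the recursive oracle
  p4 <- igraph::make_graph(~ a - b, b - c, c - d)
  s4 <- igraph::make_star(4, mode = "undirected")
  expect_equal(structural_distance(p4, s4, "exact")$distance,
               oracle_structural_distance(adj_of(p4), adj_of(s4)))

  for (r in 1:15) {
    n <- sample(5:7, 1)
    a <- rand_graph(n, runif(1, 0.3, 0.7))
    b <- rand_graph(n, runif(1, 0.3, 0.7))
    expect_equal(structural_distance(a, b, "exact")$distance,
                 oracle_structural_distance(adj_of(a), adj_of(b)))
  }
  expect_error(structural_distance(rand_graph(9, 0.5), rand_graph(9, 0.5),
                                   "exact"), "anneal")
})

test_that("annealed structural distance is bounded by exact and Hamming", {
  set.seed(64)
  for (r in 1:25) {
    a <- rand_graph(7, runif(1, 0.3, 0.7))
    b <- rand_graph(7, runif(1, 0.3, 0.7))
    ex <- structural_distance(a, b, "exact")$distance
    an <- structural_distance(a, b, "anneal", n_proposals = 2000, seed = r)
    expect_false(an$exact)
    expect_gte(an$distance, ex)
    expect_lte(an$distance, hamming_distance(a, b))
  }
})

test_that("structural distance is invariant under relabeling of either input", {
  set.seed(65)
  for (r in 1:10) {
    a <- rand_graph(6, 0.5); b <- rand_graph(6, 0.4)
    p <- sample(6)
    bp <- igraph::graph_from_adjacency_matrix(adj_of(b)[p, p],
                                              mode = "undirected")
    expect_equal(structural_distance(a, b, "exact")$distance,
                 structural_distance(a, bp, "exact")$distance)
  }
})

test_that("graph correlation endpoints and bounds behave", {
  g <- rand_graph(8, 0.5, seed = 66)
  expect_equal(graph_correlation(g, g)$correlation, 1)
  # exact mirror: complement with densities summing to 1
  A <- adj_of(g)
  comp <- igraph::graph_from_adjacency_matrix(1 - A - diag(8),
                                              mode = "undirected")
  expect_equal(graph_correlation(g, comp)$correlation, -1)
  expect_error(graph_correlation(igraph::make_empty_graph(8, directed = FALSE), g),
               "zero variance")
})

test_that("attainable correlation bounds match exhaustive overlap search", {
  # E1 = 3, E2 = 5 on N = 6: rho as a function of the pair overlap o
  N <- 6; P <- choose(N, 2); E1 <- 3; E2 <- 5
  d1 <- E1 / P; d2 <- E2 / P
  rho_of <- function(o) (o / P - d1 * d2) /
    sqrt(d1 * (1 - d1) * d2 * (1 - d2))
  feas <- max(0, E1 + E2 - P):min(E1, E2)
  g1 <- binarize(connectivity_matrix((function() {
    set.seed(67); V <- matrix(0, N, N); V[upper.tri(V)] <- runif(P); V + t(V)
  })()), "fixed_degree", 2 * E1 / N)$graph
  g2 <- binarize(connectivity_matrix((function() {
    set.seed(68); V <- matrix(0, N, N); V[upper.tri(V)] <- runif(P); V + t(V)
  })()), "fixed_degree", 2 * E2 / N)$graph
  res <- graph_correlation(g1, g2)
  expect_equal(unname(res$correlation_bounds["max"]), max(rho_of(feas)))
  expect_equal(unname(res$correlation_bounds["min"]), min(rho_of(feas)))
  expect_lt(unname(res$correlation_bounds["max"]), 1)
})

test_that("correlations stay within their attainable bounds", {
  set.seed(69)
  for (r in 1:500) {
    n <- sample(5:9, 1)
    a <- rand_graph(n, runif(1, 0.2, 0.8))
    b <- rand_graph(n, runif(1, 0.2, 0.8))
    if (igraph::ecount(a) %in% c(0, choose(n, 2))) next
    if (igraph::ecount(b) %in% c(0, choose(n, 2))) next
    res <- graph_correlation(a, b)
    expect_gte(res$correlation, res$correlation_bounds["min"] - 1e-12)
    expect_lte(res$correlation, res$correlation_bounds["max"] + 1e-12)
  }
})

test_that("coincidence similarity matches hand enumeration", {
  g <- rand_graph(8, 0.4, seed = 70)
  expect_equal(costa_similarity(g, g), 1)
  A <- adj_of(g)
  comp <- igraph::graph_from_adjacency_matrix(1 - A - diag(8),
                                              mode = "undirected")
  expect_equal(costa_similarity(g, comp), 0)
  # worked 4-node pair, entry-by-entry
  a1 <- matrix(0, 4, 4); a1[1, 2] <- a1[2, 1] <- 1; a1[3, 4] <- a1[4, 3] <- 1
  a2 <- matrix(0, 4, 4); a2[1, 2] <- a2[2, 1] <- 1; a2[1, 3] <- a2[3, 1] <- 1
  g1 <- igraph::graph_from_adjacency_matrix(a1, mode = "undirected")
  g2 <- igraph::graph_from_adjacency_matrix(a2, mode = "undirected")
  # ones of g1: 4 entries, 2 coincide; zeros of g1: 8 entries, 6 coincide
  expect_equal(costa_similarity(g1, g2), sqrt((2 / 4) * (6 / 8)))
  expect_error(costa_similarity(igraph::make_full_graph(4), g1),
               "empty or complete")
})
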