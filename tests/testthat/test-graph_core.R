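test_that("degree statistics match direct edge counts", {
  cyc <- ring_lattice(10, 2)
  ds <- degree_stats(cyc)
  expect_equal(ds$average_degree, 2)
  expect_equal(ds$max_degree, 2)
  expect_equal(ds$n_hubs, 0)

  lat <- ring_lattice(20, 4)
  expect_true(all(igraph::degree(lat) == 4))

  er <- erdos_renyi(100, 10, seed = 11)
  A <- adj_of(er)
  E <- sum(A[upper.tri(A)])
  expect_equal(degree_stats(er)$average_degree, 2 * E / 100)
  expect_equal(sum(degree_stats(er)$degree_distribution), 100)
})

test_that("degree_stats rejects empty graphs and flags weighted input", {
  expect_error(degree_stats(igraph::make_empty_graph(0)), "no nodes")
  g <- ring_lattice(10, 2)
  igraph::E(g)$weight <- runif(10)
  expect_match(degree_stats(g)$provenance$weighted_input, "nonzero pattern")
})

test_that("path length handles complete, ring and disconnected graphs", {
  expect_equal(path_length(igraph::make_full_graph(5))$L, 1)
  expect_equal(path_length(ring_lattice(10, 2))$L, 25 / 9)

  two_k3 <- igraph::disjoint_union(igraph::make_full_graph(3),
                                   igraph::make_full_graph(3))
  pl <- path_length(two_k3)
  expect_equal(pl$L, 1)
  expect_equal(pl$reachable_pair_fraction, 0.4)  # 12 of 30 ordered pairs
  expect_error(path_length(two_k3, disconnected = "error"), "2 components")
})

test_that("clustering matches closed-form cases and options behave", {
  expect_equal(clustering(igraph::make_full_graph(5)), 1)
  expect_equal(clustering(igraph::make_star(6, mode = "undirected")), 0)
  expect_equal(clustering(ring_lattice(20, 4)), 0.5)
  # excluding low-degree nodes changes the average when leaves exist
  g <- igraph::make_graph(~ a - b, b - c, c - a, c - d)
  expect_lt(clustering(g, "zero"), clustering(g, "exclude"))
})

test_that("path length and clustering agree with brute-force oracles", {
  set.seed(101)
  for (r in 1:60) {
    n <- sample(4:8, 1)
    g <- rand_graph(n, runif(1, 0.25, 0.8))
    A <- adj_of(g)
    if (sum(A) == 0) next
    o <- oracle_path_length(A)
    pl <- path_length(g)
    expect_equal(pl$L, o$L)
    expect_equal(pl$reachable_pair_fraction, o$frac)
    if (n >= 3) expect_equal(clustering(g), oracle_clustering(A))
  }
})

test_that("synchronizability and central point dominance match anchors", {
  k6 <- spectral_and_centrality(igraph::make_full_graph(6))
  expect_equal(k6$synchronizability, 1)
  star <- spectral_and_centrality(igraph::make_star(6, mode = "undirected"))
  expect_equal(star$central_point_dominance, 1)
  cyc <- spectral_and_centrality(ring_lattice(8, 2))
  expect_equal(cyc$central_point_dominance, 0)
  # synchronizability >= 1, equality only for complete graphs
  for (n in 4:8) {
    expect_equal(spectral_and_centrality(igraph::make_full_graph(n))$synchronizability, 1)
    expect_gt(spectral_and_centrality(ring_lattice(n, 2))$synchronizability, 1)
  }
  two_k3 <- igraph::disjoint_union(igraph::make_full_graph(3),
                                   igraph::make_full_graph(3))
  expect_error(spectral_and_centrality(two_k3), "disconnected")
})

test_that("closed-form measures match simulation in their validity range", {
  expect_equal(analytic_measures("lattice", 200, 4)$C_closed_form, 0.5)
  expect_equal(analytic_measures("lattice", 200, 4)$C_closed_form,
               clustering(ring_lattice(200, 4)))
  # lattice L linear in N
  l100 <- analytic_measures("lattice", 100, 4)$L_closed_form
  l200 <- analytic_measures("lattice", 200, 4)$L_closed_form
  expect_equal(l200 / l100, 2)
  # ER path length ~ ln(N)/ln(k), within 10% of simulation
  sim <- mean(vapply(1:20, function(s)
    path_length(erdos_renyi(1000, 10, seed = s))$L, numeric(1)))
  cf <- analytic_measures("erdos_renyi", 1000, 10)$L_closed_form
  expect_lt(abs(sim - cf) / sim, 0.10)
  # WS closed form reduces to the lattice at p = 0
  expect_equal(analytic_measures("watts_strogatz", 100, 10, p = 0)$L_closed_form,
               analytic_measures("lattice", 100, 10)$L_closed_form)
  expect_equal(analytic_measures("watts_strogatz", 100, 10, p = 0)$C_closed_form,
               analytic_measures("lattice", 100, 10)$C_closed_form)
})

test_that("closed forms reject out-of-range parameters", {
  expect_error(analytic_measures("lattice", 8, 4), "N > 2k")
  expect_error(analytic_measures("erdos_renyi", 100, 1), "k > 1")
  expect_error(analytic_measures("watts_strogatz", 100, 10, p = 2), "p in")
})

test_that("ER ensembles show the expected N,k trends", {
  mean_cl <- function(N, k, reps = 60) {
    v <- vapply(seq_len(reps), function(s) {
      g <- erdos_renyi(N, k, seed = 1000 + 7 * s + N)
      c(path_length(g)$L, clustering(g))
    }, numeric(2))
    rowMeans(v)
  }
  a <- mean_cl(60, 8); b <- mean_cl(120, 8)
  expect_gt(b[1], a[1])  # L grows with N at fixed k
  expect_lt(b[2], a[2])  # C falls with N at fixed k
  c1 <- mean_cl(100, 6); c2 <- mean_cl(100, 12)
  expect_lt(c2[1], c1[1])  # L falls with k at fixed N
  expect_gt(c2[2], c1[2])  # C grows with k at fixed N
  # fixed density: both approximately constant
  d1 <- mean_cl(80, 8); d2 <- mean_cl(160, 16)
  expect_lt(abs(d1[1] - d2[1]) / d1[1], 0.15)
  expect_lt(abs(d1[2] - d2[2]) / d1[2], 0.15)
})
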