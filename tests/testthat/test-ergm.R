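stat_labels <- c("edges", "mutual", "asym", "triad_201", "triad_021C",
                 "k_instar", "k_outstar", "k_cycle")

# brute-force statistic counts from the adjacency matrix
oracle_stats <- function(A) {
  n <- nrow(A)
  mutual <- sum(A[upper.tri(A)] & t(A)[upper.tri(A)])
  asym <- sum(xor(A[upper.tri(A)], t(A)[upper.tri(A)]))
  tc <- igraph::triad_census(
    igraph::graph_from_adjacency_matrix(A, mode = "directed"))
  c(edges = sum(A), mutual = mutual, asym = asym,
    triad_201 = tc[11], triad_021C = tc[6],
    k_instar = sum(choose(colSums(A), 2)),
    k_outstar = sum(choose(rowSums(A), 2)),
    k_cycle = sum(diag(A %*% A %*% A)) / 3)
}

test_that("model statistics equal brute-force subgraph counts", {
  full3 <- igraph::make_full_graph(3, directed = TRUE)
  expect_equal(unname(ergm_statistics(full3, "edges")), 6)
  # two mutual dyads sharing a node, no third-pair arcs: one 201 triad
  A <- matrix(0L, 3, 3)
  A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1L
  g201 <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
  expect_equal(unname(ergm_statistics(g201, "triad_201")), 1)
  set.seed(111)
  for (r in 1:30) {
    g <- rand_digraph(6, runif(1, 0.15, 0.7))
    expect_equal(unname(ergm_statistics(g, stat_labels)),
                 unname(oracle_stats(adj_of(g))))
  }
  expect_error(ergm_statistics(rand_graph(5, 0.5), "edges"), "directed")
  expect_error(ergm_statistics(rand_digraph(5, 0.5), "nope"), "unknown")
})

test_that("change statistics agree with from-scratch differences", {
  set.seed(112)
  for (r in 1:200) {
    n <- sample(4:8, 1)
    g <- rand_digraph(n, runif(1, 0.2, 0.7))
    A <- adj_of(g)
    ij <- sample(n, 2)
    A0 <- A; A0[ij[1], ij[2]] <- 0
    A1 <- A; A1[ij[1], ij[2]] <- 1
    g0 <- igraph::graph_from_adjacency_matrix(A0, mode = "directed")
    d <- netcompare:::ergm_change_statistics(g0, ij[1], ij[2], stat_labels)
    expect_equal(unname(d),
                 unname(oracle_stats(A1) - oracle_stats(A0)))
  }
})

test_that("the sampler reproduces Bernoulli edge models", {
  m0 <- ergm_model("edges", 0)
  s0 <- ergm_sample(m0, 12, n_keep = 400, seed = 113)
  dens <- s0$trace[, 1] / 132
  se <- sd(dens) / sqrt(length(dens))  # conservative: samples correlated
  expect_lt(abs(mean(dens) - 0.5), max(3 * se, 0.02))

  m2 <- ergm_model("edges", qlogis(0.2))
  s2 <- ergm_sample(m2, 12, n_keep = 400, seed = 114)
  dens2 <- s2$trace[, 1] / 132
  expect_lt(abs(mean(dens2) - 0.2), max(3 * sd(dens2) / 20, 0.02))

  # determinism under the same seed
  a <- ergm_sample(m2, 10, n_keep = 50, seed = 115)
  b <- ergm_sample(m2, 10, n_keep = 50, seed = 115)
  expect_identical(a$trace, b$trace)
})

test_that("the theta = 0 chain matches the exact binomial law", {
  # odd thin so that accept-all chains alternate edge-count parity
  s <- ergm_sample(ergm_model("edges", 0), 8, n_keep = 2000, thin = 501,
                   seed = 116)
  counts <- s$trace[, 1]
  m <- 8 * 7
  breaks <- c(-Inf, qbinom(c(0.2, 0.4, 0.6, 0.8), m, 0.5), Inf)
  obs <- table(cut(counts, breaks))
  p_cells <- diff(c(0, pbinom(qbinom(c(0.2, 0.4, 0.6, 0.8), m, 0.5), m, 0.5), 1))
  chi <- suppressWarnings(chisq.test(obs, p = p_cells))
  expect_gt(chi$p.value, 0.01)
})

test_that("edges-only MLE matches the logit of the density", {
  set.seed(117)
  g <- rand_digraph(20, 0.25)
  f <- ergm_fit(g, "edges", seed = 118, samples_per_iteration = 1500)
  d <- igraph::ecount(g) / 380
  expect_lt(abs(f$model$theta - qlogis(d)), 3 * f$std_errors)
  # residual deviance matches the exact Bernoulli log-likelihood
  exact_ll <- igraph::ecount(g) * log(d) + (380 - igraph::ecount(g)) * log(1 - d)
  expect_lt(abs(f$residual_deviance - (-2 * exact_ll)),
            max(6 * f$loglik_mc_se, 1))
  expect_equal(f$aic, 2 - 2 * f$loglik_estimate)
  expect_equal(f$explained_deviance, f$null_deviance - f$residual_deviance)
})

test_that("exact-enumeration MLE agrees with MCMC-MLE on 4-node digraphs", {
  set.seed(119)
  for (r in 1:3) {
    ok <- function(g) {
      # statistics strictly inside the convex hull: all three dyad types
      # present, otherwise the MLE sits at infinity
      d <- dyad_census_counts(g)
      all(d > 0) && igraph::ecount(g) %in% 2:10
    }
    g <- rand_digraph(4, 0.5)
    while (!ok(g)) g <- rand_digraph(4, 0.5)
    ex <- ergm_exact_mle(g, c("edges", "asym"))
    f <- ergm_fit(g, c("edges", "asym"), seed = 120 + r,
                  samples_per_iteration = 4000, loglik = FALSE)
    expect_lt(max(abs(f$model$theta - ex$theta)), 0.05)
  }
})

test_that("boundary statistics are rejected", {
  A <- matrix(0L, 5, 5); A[1, 2] <- 1L  # no mutual dyads at all
  g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
  expect_error(ergm_fit(g, c("edges", "mutual")), "boundary")
})

test_that("degeneracy is flagged when sampled statistics cannot reach the data", {
  # strong positive coefficients on many statistics drive the sampled
  # distribution to the complete graph, away from a sparse observation
  set.seed(121)
  g <- rand_digraph(12, 0.15)
  fit <- structure(list(model = ergm_model(c("edges", "k_instar"), c(2, 2)),
                        degenerate = TRUE, n_nodes = 12,
                        loglik_estimate = NA_real_),
                   class = "ergm_fit")
  # deviances degrade gracefully for a degenerate fit
  dev <- ergm_deviance(fit, g)
  expect_true(is.na(dev$residual_deviance))
  expect_equal(dev$null_deviance, 2 * 132 * log(2))
  expect_error(ergm_gof(fit, g), "degenerate")
})

test_that("null deviance and df take their closed-form values", {
  g30 <- rand_digraph(30, 0.3, seed = 122)
  fit <- list(model = ergm_model("edges", 0), degenerate = FALSE,
              loglik_estimate = -400)
  class(fit) <- "ergm_fit"
  dev <- ergm_deviance(fit, g30)
  expect_equal(round(dev$null_deviance), 1206)
  expect_equal(unname(dev$df["total"]), 870)
})

test_that("Akaike weights favour the smallest AIC and sum to one", {
  w <- akaike_weights(c(100, 102, 110))
  expect_equal(sum(w), 1)
  expect_equal(which.max(w), 1L)
})

test_that("goodness of fit honours the moment condition at the MLE", {
  set.seed(123)
  g <- rand_digraph(16, 0.25)
  f <- ergm_fit(g, c("edges", "asym"), seed = 124,
                samples_per_iteration = 2000, loglik = FALSE)
  gof <- ergm_gof(f, g, n_sim = 60, seed = 125)
  # moment condition: simulated means close to observed on the scale of the
  # sampled-statistic spread (envelope width ~ 3.92 SDs)
  sim_sd <- (gof$statistics$upper - gof$statistics$lower) / 3.92
  expect_true(all(abs(gof$statistics$sim_mean - gof$statistics$observed) <=
                    3 * pmax(sim_sd, 1)))
  expect_true(all(gof$statistics$inside))
  expect_equal(nrow(gof$triad_census), 16)
  # misspecified model: lattice-like mutuality with an edges-only model
  A <- adj_of(ring_lattice(16, 4))
  gl <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
  fl <- ergm_fit(gl, "edges", seed = 126, samples_per_iteration = 1500,
                 loglik = FALSE)
  gof_l <- ergm_gof(fl, gl, n_sim = 60, seed = 127)
  expect_false(all(gof_l$triad_census$inside))
})

test_that("parameter recovery covers the truth at the stated rate", {
  truth <- c(-1, 0.2)
  labs <- c("asym", "triad_201")
  model <- ergm_model(labs, truth)
  covered <- matrix(NA, 8, 2)
  for (t in 1:8) {
    sim <- ergm_sample(model, 30, n_burn = 30 * 29 * 40, n_keep = 1,
                       seed = 920 + t)$final
    f <- ergm_fit(sim, labs, seed = 940 + t, samples_per_iteration = 1500,
                  loglik = FALSE)
    covered[t, ] <- abs(f$model$theta - truth) <= 3 * f$std_errors
  }
  expect_gte(mean(covered), 0.9)
})
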