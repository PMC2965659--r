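# Baseline-model comparison of networks differing in N and k, rewiring
# probability estimation, and edge-removal estimation of k-dependence.

#' Generator specification
#'
#' Bundle of topology + parameters used by the baseline-comparison and
#' simulation machinery.
#'
#' @param topology one of `"lattice"`, `"erdos_renyi"`, `"watts_strogatz"`,
#'   `"barabasi_albert"`.
#' @param N,k,p,m model parameters (see the individual generators).
#' @return a `generator_spec` list.
#' @export
generator_spec <- function(topology = c("lattice", "erdos_renyi",
                                        "watts_strogatz", "barabasi_albert"),
                           N, k = NULL, p = NULL, m = NULL) {
  topology <- match.arg(topology)
  structure(list(topology = topology, N = N, k = k, p = p, m = m),
            class = "generator_spec")
}

#' Draw a graph from a generator specification
#'
#' @param spec a [generator_spec()].
#' @param seed optional RNG seed.
#' @return an igraph object.
#' @export
generate_graph <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  with_seed(seed, switch(spec$topology,
    lattice = ring_lattice(spec$N, spec$k),
    erdos_renyi = erdos_renyi(spec$N, spec$k),
    watts_strogatz = watts_strogatz(spec$N, spec$k, spec$p),
    barabasi_albert = barabasi_albert(spec$N, spec$m)))
}

# Ensemble-mean C and L over n_reps draws of WS(N, k, p) (k rounded to the
# nearest even integer for the generator), used by estimate_p_rewire.
ws_ensemble_cl <- function(N, k, p, n_reps, weights = NULL) {
  k_even <- max(2, 2 * round(k / 2))
  Cs <- numeric(n_reps); Ls <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    g <- if (is.null(weights)) watts_strogatz(N, k_even, p)
         else lattice_with_weights(weights, N, p)
    Cs[r] <- clustering(g)
    Ls[r] <- path_length(g)$L
  }
  c(C = mean(Cs), L = mean(Ls))
}

# Ensemble-mean C and L of the matched random reference: Erdos-Renyi with
# the same N and E, or (weighted) the same weights placed on random pairs.
random_ensemble_cl <- function(N, E, n_reps, weights = NULL) {
  Cs <- numeric(n_reps); Ls <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    g <- if (is.null(weights)) igraph::sample_gnm(N, E) else {
      pairs <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
      sel <- pairs[sample.int(nrow(pairs), length(weights)), , drop = FALSE]
      gg <- igraph::make_empty_graph(N, directed = FALSE)
      gg <- igraph::add_edges(gg, t(sel))
      igraph::E(gg)$weight <- sample(weights)
      gg
    }
    Cs[r] <- clustering(g)
    Ls[r] <- path_length(g)$L
  }
  c(C = mean(Cs), L = mean(Ls))
}

#' Estimate the rewiring probability of a small-world baseline model
#'
#' Fits a Watts-Strogatz rewiring probability to an observed network by
#' least squares on the small-world index: for each candidate `p`, the
#' ensemble-mean SW of simulated networks matched to the observed `N` and
#' `k` (or, for weighted inputs, carrying the observed weight multiset via
#' [lattice_with_weights()]) is compared with the observed SW, and the
#' minimizer is returned. SW values are formed from ensemble means of C and
#' L, normalized by a shared matched random reference.
#'
#' @param g the observed graph (unweighted, or weighted -- see above).
#' @param n_reps simulated networks per grid point (default 200).
#' @param p_grid candidate rewiring probabilities (default 0.01 to 1 in
#'   steps of 0.01).
#' @param seed optional RNG seed.
#' @return list with `p_hat`, `sw_observed`, the `sw_curve` over the grid,
#'   and a `boundary` flag set when the observed SW lies outside the range
#'   simulated anywhere on the grid.
#' @export
estimate_p_rewire <- function(g, n_reps = 200,
                              p_grid = seq(0.01, 1, by = 0.01),
                              seed = NULL) {
  check_graph(g, directed = FALSE)
  N <- igraph::vcount(g); E <- igraph::ecount(g)
  k <- 2 * E / N
  weights <- if (is_weighted_graph(g)) igraph::E(g)$weight else NULL
  with_seed(seed, {
    ref <- random_ensemble_cl(N, E, n_reps, weights)
    sw_of <- function(C, L) (C / ref["C"]) / (L / ref["L"])
    sw_obs <- unname(sw_of(clustering(g), path_length(g)$L))
    sw_curve <- vapply(p_grid, function(p) {
      cl <- ws_ensemble_cl(N, k, p, n_reps, weights)
      unname(sw_of(cl["C"], cl["L"]))
    }, numeric(1))
    i <- which.min((sw_curve - sw_obs)^2)
    outside <- sw_obs > max(sw_curve) || sw_obs < min(sw_curve)
    boundary <- outside && (i == 1L || i == length(p_grid))
    if (boundary)
      warnf("observed SW (%.3g) outside simulated range; returning boundary p",
            sw_obs)
    list(p_hat = p_grid[i], sw_observed = sw_obs,
         p_grid = p_grid, sw_curve = sw_curve, boundary = boundary)
  })
}

#' Baseline-model test for a difference in a graph measure
#'
#' Tests whether the observed difference `g(network 1) - g(network 2)` in a
#' graph measure could be produced by size and density effects alone: pairs
#' of networks are simulated from a baseline model matched to the two
#' observed `(N, k)` configurations, yielding a distribution of simulated
#' differences and its 95 percent interval. An observed difference outside
#' the interval cannot be attributed exclusively to mere size effects.
#'
#' @param g1,g2 observed graphs.
#' @param measure `"L"`, `"C"`, `"SW"`, or a function of a graph.
#' @param model list of two [generator_spec()]s matched to `g1` and `g2`.
#' @param n_reps number of simulated pairs (default 2000).
#' @param sw_surrogates surrogate draws per SW evaluation when
#'   `measure = "SW"` (kept modest since SW is recomputed `2 n_reps` times).
#' @param seed optional RNG seed.
#' @param retry_cap resampling cap when the measure fails on a draw.
#' @return list with `observed_delta`, `delta_samples`, `ci95`, `inside_ci`,
#'   `model`, `n_reps`, `seed`.
#' @export
delta_distribution_test <- function(g1, g2, measure = "C", model,
                                    n_reps = 2000, sw_surrogates = 20,
                                    seed = NULL, retry_cap = 10) {
  stopifnot(length(model) == 2, inherits(model[[1]], "generator_spec"),
            inherits(model[[2]], "generator_spec"))
  if (n_reps < 100) stopf("n_reps must be >= 100 for a stable 95%% interval")
  fn <- if (is.function(measure)) measure else switch(measure,
    L = function(g) path_length(g)$L,
    C = clustering,
    SW = function(g) small_world_index(g, n_surrogates = sw_surrogates)$sw,
    stopf("unknown measure"))
  with_seed(seed, {
    observed <- fn(g1) - fn(g2)
    one <- function(spec) {
      for (try in seq_len(retry_cap)) {
        v <- tryCatch(fn(generate_graph(spec)), error = function(e) NULL)
        if (!is.null(v) && is.finite(v)) return(v)
      }
      stopf("measure failed on %d consecutive simulated draws", retry_cap)
    }
    deltas <- vapply(seq_len(n_reps),
                     function(r) one(model[[1]]) - one(model[[2]]),
                     numeric(1))
    ci <- unname(quantile(deltas, c(0.025, 0.975)))
    list(observed_delta = observed, delta_samples = deltas,
         ci95 = ci, inside_ci = observed >= ci[1] && observed <= ci[2],
         model = model, n_reps = n_reps, seed = seed)
  })
}

#' Estimate the k-dependence of L and C by random edge removal
#'
#' Removes edges uniformly at random, stepwise decreasing the average
#' degree, and recomputes path length and clustering at each step; repeated
#' `n_reps` times to give mean and SD curves. Note this estimate is biased
#' toward random-network values: removing local edges destroys clustering
#' among direct neighbors, so the removal-estimated C at a given `k` lies
#' below the C of a network generated at that `k` directly. If the graph
#' carries the `rewired` edge attribute (see [watts_strogatz()]), the mean
#' number of local (non-rewired) edges removed at each step is reported.
#'
#' @param g an unweighted connected igraph object.
#' @param k_steps decreasing average-degree targets, all below the current
#'   average degree.
#' @param n_reps repetitions (default 200).
#' @param seed optional RNG seed.
#' @return list with `k_grid` (starting at the source average degree),
#'   `L_mean`, `L_sd`, `C_mean`, `C_sd`, optionally `local_removed_mean`,
#'   and `origin`.
#' @export
estimate_k_dependence <- function(g, k_steps, n_reps = 200, seed = NULL) {
  check_graph(g, weighted = FALSE)
  N <- igraph::vcount(g); E <- igraph::ecount(g)
  k0 <- 2 * E / N
  if (any(diff(k_steps) >= 0) && length(k_steps) > 1)
    stopf("k_steps must be strictly decreasing")
  if (any(k_steps >= k0)) stopf("all k_steps must be below the current k (%g)", k0)
  targets_E <- round(k_steps * N / 2)
  has_local <- "rewired" %in% igraph::edge_attr_names(g)
  local_flag <- if (has_local) !igraph::E(g)$rewired else NULL
  with_seed(seed, {
    n_step <- length(k_steps)
    Lm <- matrix(NA_real_, n_reps, n_step)
    Cm <- matrix(NA_real_, n_reps, n_step)
    loc <- if (has_local) matrix(NA_real_, n_reps, n_step) else NULL
    for (r in seq_len(n_reps)) {
      removal_order <- sample.int(E)
      for (s in seq_len(n_step)) {
        drop <- removal_order[seq_len(E - targets_E[s])]
        gs <- igraph::delete_edges(g, drop)
        Lm[r, s] <- path_length(gs)$L
        Cm[r, s] <- clustering(gs)
        if (has_local) loc[r, s] <- sum(local_flag[drop])
      }
    }
    out <- list(k_grid = c(k0, 2 * targets_E / N),
                L_mean = c(path_length(g)$L, colMeans(Lm)),
                L_sd = c(0, apply(Lm, 2, stats::sd)),
                C_mean = c(clustering(g), colMeans(Cm)),
                C_sd = c(0, apply(Cm, 2, stats::sd)),
                n_reps = n_reps, origin = c(N = N, k = k0))
    if (has_local) out$local_removed_mean <- c(0, colMeans(loc))
    out
  })
}
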