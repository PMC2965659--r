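# Exponential random graph models with motif statistics: statistics and
# change statistics, Metropolis sampling, maximum pseudo-likelihood
# initialization, MCMC maximum likelihood, path-sampling log-likelihood,
# deviances/AIC and goodness of fit. The model is
#   P(Y = y) = exp(sum_mu theta_mu g_mu(y)) / n(theta)
# with no implicit edges term: the sign of each theta is relative to the
# uniform random digraph with edge probability 1/2.

ERGM_STAT_IDS <- c(edges = 0L, mutual = 1L, asym = 2L, triad_201 = 3L,
                   triad_021C = 4L, k_instar = 5L, k_outstar = 6L,
                   k_cycle = 7L)

ergm_stat_ids <- function(labels) {
  if (!length(labels)) stopf("at least one statistic is required")
  if (anyDuplicated(labels)) stopf("statistic labels must be unique")
  unknown <- setdiff(labels, names(ERGM_STAT_IDS))
  if (length(unknown))
    stopf("unknown statistic label(s): %s", paste(unknown, collapse = ", "))
  unname(ERGM_STAT_IDS[labels])
}

ergm_adjacency <- function(g) {
  check_graph(g, directed = TRUE, weighted = FALSE)
  A <- adjacency_of(g)
  storage.mode(A) <- "integer"
  A
}

#' ERGM statistics of a directed graph
#'
#' Counts of the supported model statistics: `edges` (arcs), `mutual` and
#' `asym` dyads, the triad classes `triad_201` (two mutual dyads sharing a
#' node) and `triad_021C` (directed two-path), `k_instar` / `k_outstar`
#' (2-in-stars and 2-out-stars) and `k_cycle` (directed 3-cycles).
#'
#' @param g a directed, unweighted igraph object.
#' @param labels character vector of statistic labels.
#' @return named numeric vector of counts.
#' @export
ergm_statistics <- function(g, labels) {
  A <- ergm_adjacency(g)
  stats::setNames(.ergm_stats_cpp(A, ergm_stat_ids(labels)), labels)
}

#' ERGM model specification
#'
#' @param statistics character vector of statistic labels (see
#'   [ergm_statistics()]).
#' @param theta numeric coefficient vector, one per statistic.
#' @return an `ergm_model` list.
#' @export
ergm_model <- function(statistics, theta) {
  ids <- ergm_stat_ids(statistics)
  if (length(theta) != length(statistics) || any(!is.finite(theta)))
    stopf("theta must be finite, one value per statistic")
  structure(list(statistics = statistics, theta = as.numeric(theta),
                 ids = ids), class = "ergm_model")
}

#' Sample networks from an ERGM
#'
#' Single-arc-toggle Metropolis-Hastings: a proposal toggles one ordered
#' pair and is accepted with probability `min(1, exp(theta . delta_g))`,
#' with the change statistics computed incrementally. Returns the trace of
#' the statistics for diagnostics and (optionally) the sampled graphs.
#'
#' @param model an [ergm_model()].
#' @param N number of nodes.
#' @param n_burn burn-in proposals (default `20 * N * (N-1)`).
#' @param n_keep number of recorded samples.
#' @param thin proposals between recorded samples (default `N * (N-1)`).
#' @param seed optional RNG seed.
#' @param init optional initial igraph (default: uniform random digraph,
#'   density 1/2).
#' @param keep_graphs also return each sampled graph as an igraph object.
#' @return list with `trace` (n_keep x p matrix), `final` (igraph),
#'   `graphs` (if requested) and `acceptance_rate`.
#' @export
ergm_sample <- function(model, N, n_burn = NULL, n_keep = 100, thin = NULL,
                        seed = NULL, init = NULL, keep_graphs = FALSE) {
  stopifnot(inherits(model, "ergm_model"))
  if (N < 3) stopf("N must be >= 3")
  n_burn <- n_burn %||% (20L * N * (N - 1L))
  # odd thinning: when every proposal is accepted (theta ~ 0) an even
  # number of toggles between samples would lock the edge-count parity
  thin <- thin %||% (N * (N - 1L) + 1L)
  with_seed(seed, {
    A0 <- if (is.null(init)) {
      M <- matrix(rbinom(N * N, 1, 0.5), N, N); diag(M) <- 0L
      storage.mode(M) <- "integer"; M
    } else ergm_adjacency(init)
    res <- .ergm_sample_cpp(A0, model$theta, model$ids,
                            as.integer(n_burn), as.integer(n_keep),
                            as.integer(thin), keep_graphs)
    colnames(res$trace) <- model$statistics
    out <- list(trace = res$trace,
                final = graph_from_adjacency(res$final, directed = TRUE),
                acceptance_rate = res$acceptance_rate)
    if (keep_graphs)
      out$graphs <- lapply(res$graphs, graph_from_adjacency, directed = TRUE)
    out
  })
}

# Change statistics of adding arc i -> j (1-based), the arc being absent.
ergm_change_statistics <- function(g, i, j, labels) {
  A <- ergm_adjacency(g)
  if (A[i, j] != 0) A[i, j] <- 0L
  stats::setNames(.ergm_delta_cpp(A, i - 1L, j - 1L, ergm_stat_ids(labels)),
                  labels)
}

# Maximum pseudo-likelihood estimate: logistic regression of the arc
# indicators on their change statistics.
ergm_mple <- function(g, labels) {
  A <- ergm_adjacency(g)
  d <- .ergm_mple_cpp(A, ergm_stat_ids(labels))
  fit <- suppressWarnings(glm(d$y ~ d$x - 1, family = binomial()))
  th <- unname(coef(fit))
  th[!is.finite(th)] <- 0
  pmin(pmax(th, -10), 10)  # guard against separation
}

#' Fit an ERGM by Monte-Carlo maximum likelihood
#'
#' Maximum pseudo-likelihood initialization followed by iterative
#' stochastic-approximation MCMC-MLE: at each of `n_iterations` steps,
#' networks are sampled at the current coefficients and theta is updated by
#' a damped Newton step toward the moment condition
#' `E_theta[g] = g_observed`. Standard errors come from the estimated
#' Fisher information (the covariance of the sampled statistics); the
#' log-likelihood is estimated by path sampling from the uniform model
#' (whose normalizer is known analytically). A fit whose final sampled
#' statistic distributions fail to overlap the observed values is flagged
#' degenerate.
#'
#' @param g a directed, unweighted igraph object.
#' @param labels statistic labels (see [ergm_statistics()]).
#' @param n_iterations Newton/sampling iterations (default 10).
#' @param samples_per_iteration networks sampled per iteration (default
#'   1e4; `full_scale = TRUE` restores 1e5).
#' @param thin proposals between sampled networks (default `N(N-1)/10`,
#'   at least 50).
#' @param seed optional RNG seed.
#' @param full_scale use the full-scale sampling schedule.
#' @param loglik also estimate the log-likelihood, deviances and AIC
#'   (adds path-sampling runs; disable for speed in simulations).
#' @return an `ergm_fit` list: `model` (with estimated theta),
#'   `std_errors`, `observed`, `sampled_mean`, `loglik_estimate`,
#'   `loglik_mc_se`, `aic`, `null_deviance`, `residual_deviance`,
#'   `explained_deviance`, `df`, `degenerate`, `degeneracy_note`,
#'   `acceptance_rate`, `seed`.
#' @export
ergm_fit <- function(g, labels, n_iterations = 10,
                     samples_per_iteration = 1e4, thin = NULL, seed = NULL,
                     full_scale = FALSE, loglik = TRUE) {
  A <- ergm_adjacency(g)
  N <- nrow(A)
  ids <- ergm_stat_ids(labels)
  p <- length(labels)
  if (full_scale) samples_per_iteration <- 1e5
  g_obs <- .ergm_stats_cpp(A, ids)
  if (any(g_obs == 0))
    stopf("observed statistic(s) on the boundary (zero): %s",
          paste(labels[g_obs == 0], collapse = ", "))
  if ("edges" %in% labels && g_obs[match("edges", labels)] == N * (N - 1))
    stopf("observed graph is complete: edges statistic on the boundary")
  # half a dyad sweep between samples: short thinning lets slow-mixing triad
  # statistics underestimate their variance, and with it the standard errors
  thin <- thin %||% (max(50L, as.integer(N * (N - 1) / 2)) + 1L)
  seeds <- derive_seeds(seed, n_iterations + 2)
  theta <- ergm_mple(g, labels)
  trace <- NULL; acc <- NA_real_
  for (it in seq_len(n_iterations)) {
    smp <- ergm_sample(ergm_model(labels, theta), N,
                       n_burn = 100L * thin,
                       n_keep = as.integer(samples_per_iteration),
                       thin = thin, seed = seeds[[it]], init = g)
    trace <- smp$trace; acc <- smp$acceptance_rate
    mu <- colMeans(trace)
    V <- stats::cov(trace)
    Vr <- V + diag(1e-8 + 1e-6 * diag(V), p)
    step <- tryCatch(solve(Vr, g_obs - mu), error = function(e) rep(0, p))
    nrm <- sqrt(sum(step^2))
    if (nrm > 2) step <- step * 2 / nrm  # trust region
    theta <- theta + 0.8 * step
  }
  # final sample at the estimate, for SEs and degeneracy diagnostics
  smp <- ergm_sample(ergm_model(labels, theta), N, n_burn = 100L * thin,
                     n_keep = as.integer(samples_per_iteration), thin = thin,
                     seed = seeds[[n_iterations + 1]], init = g)
  trace <- smp$trace
  V <- stats::cov(trace)
  se <- tryCatch(sqrt(diag(solve(V + diag(1e-8, p)))),
                 error = function(e) rep(NA_real_, p))
  outside <- vapply(seq_len(p), function(s)
    g_obs[s] < min(trace[, s]) || g_obs[s] > max(trace[, s]), logical(1))
  degenerate <- any(outside)
  note <- if (degenerate)
    sprintf("sampled distribution does not overlap observed value for: %s",
            paste(labels[outside], collapse = ", ")) else NA_character_
  fit <- structure(list(
    model = ergm_model(labels, theta),
    std_errors = stats::setNames(se, labels),
    observed = stats::setNames(g_obs, labels),
    sampled_mean = stats::setNames(colMeans(trace), labels),
    n_nodes = N, degenerate = degenerate, degeneracy_note = note,
    acceptance_rate = smp$acceptance_rate,
    n_iterations = n_iterations,
    samples_per_iteration = samples_per_iteration,
    seed = seed), class = "ergm_fit")
  if (loglik && !degenerate) {
    ll <- ergm_loglik(fit$model, g, n_keep = min(2000L,
                        as.integer(samples_per_iteration)),
                      seed = seeds[[n_iterations + 2]])
    fit$loglik_estimate <- ll$loglik
    fit$loglik_mc_se <- ll$mc_se
    dev <- ergm_deviance(fit, g)
    fit[names(dev)] <- dev
  } else {
    fit$loglik_estimate <- NA_real_
    fit$aic <- NA_real_
  }
  fit
}

#' @export
print.ergm_fit <- function(x, ...) {
  cat(sprintf("ERGM fit on %d nodes%s\n", x$n_nodes,
              if (x$degenerate) " [DEGENERATE]" else ""))
  tab <- data.frame(statistic = x$model$statistics,
                    observed = x$observed,
                    theta = x$model$theta,
                    std_error = x$std_errors, row.names = NULL)
  print(tab, digits = 4)
  if (is.finite(x$aic %||% NA))
    cat(sprintf("loglik %.2f (MC se %.2f), AIC %.1f, explained deviance %.0f (%d)\n",
                x$loglik_estimate, x$loglik_mc_se, x$aic,
                x$explained_deviance, length(x$model$theta)))
  invisible(x)
}

# Path-sampling estimate of the log-likelihood: bridges from theta = 0
# (log normalizer N(N-1) log 2, samples drawn directly) to theta.
ergm_loglik <- function(model, g, n_bridges = 10, n_keep = 2000,
                        seed = NULL) {
  A <- ergm_adjacency(g)
  N <- nrow(A)
  ids <- model$ids
  p <- length(ids)
  g_obs <- .ergm_stats_cpp(A, ids)
  thin <- max(50L, as.integer(N * (N - 1) / 2)) + 1L
  seeds <- derive_seeds(seed, n_bridges)
  log_n_ratio <- 0
  var_sum <- 0
  for (b in seq_len(n_bridges)) {
    th_b <- model$theta * (b - 1) / n_bridges
    dth <- model$theta / n_bridges
    G <- if (b == 1) {
      with_seed(seeds[[1]], {
        S <- min(n_keep, 2000L)
        out <- matrix(NA_real_, S, p)
        for (r in seq_len(S)) {
          M <- matrix(rbinom(N * N, 1, 0.5), N, N); diag(M) <- 0L
          storage.mode(M) <- "integer"
          out[r, ] <- .ergm_stats_cpp(M, ids)
        }
        out
      })
    } else {
      ergm_sample(ergm_model(model$statistics, th_b), N,
                  n_burn = 50L * thin, n_keep = as.integer(n_keep),
                  thin = thin, seed = seeds[[b]], init = g)$trace
    }
    w <- exp(as.numeric(G %*% dth))
    mw <- mean(w)
    log_n_ratio <- log_n_ratio + log(mw)
    var_sum <- var_sum + stats::var(w) / (length(w) * mw^2)
  }
  log_n <- N * (N - 1) * log(2) + log_n_ratio
  list(loglik = sum(model$theta * g_obs) - log_n, mc_se = sqrt(var_sum))
}

#' Deviances and AIC of an ERGM fit
#'
#' The null model assigns probability 1/2 to each of the `N(N-1)` possible
#' arcs, so the null deviance is `2 N(N-1) ln 2` with `N(N-1)` degrees of
#' freedom (1206 with 870 df for a 30-node digraph). The residual deviance
#' is `-2` times the estimated log-likelihood; explained deviance is their
#' difference, with one df per model statistic.
#'
#' @param fit an `ergm_fit` (non-degenerate for the residual quantities).
#' @param g the observed graph.
#' @return list with `null_deviance`, `residual_deviance`,
#'   `explained_deviance`, `aic`, `df` (named: total, model).
#' @export
ergm_deviance <- function(fit, g) {
  N <- igraph::vcount(g)
  null_dev <- 2 * N * (N - 1) * log(2)
  p <- length(fit$model$theta)
  if (isTRUE(fit$degenerate) || !is.finite(fit$loglik_estimate %||% NA))
    return(list(null_deviance = null_dev, residual_deviance = NA_real_,
                explained_deviance = NA_real_, aic = NA_real_,
                df = c(total = N * (N - 1), model = p)))
  resid <- -2 * fit$loglik_estimate
  list(null_deviance = null_dev, residual_deviance = resid,
       explained_deviance = null_dev - resid,
       aic = 2 * p - 2 * fit$loglik_estimate,
       df = c(total = N * (N - 1), model = p))
}

#' Akaike weights
#'
#' Converts a vector of AIC values into model weights
#' `exp(-dAIC/2) / sum(exp(-dAIC/2))`.
#'
#' @param aic numeric vector of AIC values.
#' @return numeric vector of weights summing to 1.
#' @export
akaike_weights <- function(aic) {
  d <- aic - min(aic, na.rm = TRUE)
  w <- exp(-d / 2)
  w / sum(w, na.rm = TRUE)
}

#' Exact maximum likelihood for tiny digraphs
#'
#' Enumerates all `2^(N(N-1))` digraphs (N <= 4) and maximizes the exact
#' likelihood; a reference point for validating the MCMC fit.
#'
#' @param g a directed, unweighted igraph object with at most 4 nodes.
#' @param labels statistic labels.
#' @return list with `theta`, `loglik`.
#' @export
ergm_exact_mle <- function(g, labels) {
  A <- ergm_adjacency(g)
  N <- nrow(A)
  if (N > 4) stopf("exact enumeration is limited to N <= 4")
  ids <- ergm_stat_ids(labels)
  p <- length(ids)
  m <- N * (N - 1)
  pos <- which(row(A) != col(A))
  G <- matrix(NA_real_, 2^m, p)
  M <- matrix(0L, N, N)
  for (code in 0:(2^m - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(m)]
    M[pos] <- bits
    G[code + 1, ] <- .ergm_stats_cpp(M, ids)
  }
  g_obs <- .ergm_stats_cpp(A, ids)
  nll <- function(th) {
    e <- G %*% th
    mx <- max(e)
    -(sum(th * g_obs) - (mx + log(sum(exp(e - mx)))))
  }
  opt <- optim(rep(0, p), nll, method = "BFGS")
  list(theta = stats::setNames(opt$par, labels), loglik = -opt$value)
}

#' Goodness of fit of an ERGM
#'
#' Simulates networks at the fitted coefficients and compares the observed
#' network against the simulated distributions of the model statistics, the
#' full triad census, and the in- and out-degree distributions, with 95
#' percent simulation envelopes.
#'
#' @param fit an `ergm_fit` (non-degenerate).
#' @param g the observed graph.
#' @param n_sim number of simulated networks (default 100).
#' @param seed optional RNG seed.
#' @return list of data frames `statistics`, `triad_census`, `in_degree`,
#'   `out_degree`, each with observed values, simulated means, envelope
#'   bounds and an `inside` flag.
#' @export
ergm_gof <- function(fit, g, n_sim = 100, seed = NULL) {
  stopifnot(inherits(fit, "ergm_fit"))
  if (isTRUE(fit$degenerate)) stopf("fit is degenerate; GOF unavailable")
  N <- igraph::vcount(g)
  thin <- max(50L, as.integer(N * (N - 1) / 2)) + 1L
  smp <- ergm_sample(fit$model, N, n_burn = 100L * thin, n_keep = n_sim,
                     thin = thin, seed = seed, init = g, keep_graphs = TRUE)
  envelope <- function(obs, sim_mat, labels) {
    lo <- apply(sim_mat, 2, quantile, 0.025)
    hi <- apply(sim_mat, 2, quantile, 0.975)
    data.frame(label = labels, observed = obs, sim_mean = colMeans(sim_mat),
               lower = lo, upper = hi,
               inside = obs >= lo & obs <= hi, row.names = NULL)
  }
  sim_stats <- smp$trace
  sim_census <- t(vapply(smp$graphs, triad_census_counts,
                         numeric(16)))
  degs <- function(gg, mode) tabulate(igraph::degree(gg, mode = mode) + 1,
                                      nbins = N)
  sim_in <- t(vapply(smp$graphs, degs, numeric(N), mode = "in"))
  sim_out <- t(vapply(smp$graphs, degs, numeric(N), mode = "out"))
  list(statistics = envelope(unname(fit$observed), sim_stats,
                             fit$model$statistics),
       triad_census = envelope(unname(triad_census_counts(g)), sim_census,
                               TRIAD_LABELS),
       in_degree = envelope(degs(g, "in"), sim_in, 0:(N - 1)),
       out_degree = envelope(degs(g, "out"), sim_out, 0:(N - 1)),
       n_sim = n_sim)
}
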