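#' Degree statistics of a graph
#'
#' Computes the average degree \eqn{k}, the degree distribution, the maximum
#' degree and the number of hubs. For an undirected graph the average degree
#' is \eqn{2E/N}. Weighted graphs are handled on their nonzero pattern, with
#' a note recorded in the provenance.
#'
#' @param g an igraph object without self-loops.
#' @param hub_rule how a node qualifies as a hub. The default
#'   `"mean_plus_2sd"` counts nodes whose degree exceeds the mean degree plus
#'   twice the standard deviation of the degree distribution. Alternatively a
#'   function of the degree vector returning a logical vector.
#' @return a list with elements `average_degree`, `degree_distribution`
#'   (a table over observed degrees summing to \eqn{N}), `max_degree`,
#'   `n_hubs` and `provenance`.
#' @examples
#' g <- ring_lattice(20, 4)
#' degree_stats(g)$average_degree
#' @export
degree_stats <- function(g, hub_rule = "mean_plus_2sd") {
  check_graph(g)
  prov <- list(hub_rule = if (is.function(hub_rule)) "custom" else hub_rule)
  if (is_weighted_graph(g)) prov$weighted_input <-
      "degrees computed on the nonzero pattern of a weighted graph"
  deg <- igraph::degree(g, loops = FALSE)
  if (is.character(hub_rule)) {
    hub_rule <- match.arg(hub_rule, "mean_plus_2sd")
    cut <- mean(deg) + 2 * stats::sd(deg)
    hubs <- is.finite(cut) & deg > cut
  } else {
    hubs <- hub_rule(deg)
  }
  list(average_degree = mean(deg),
       degree_distribution = table(factor(deg, levels = 0:max(deg))),
       max_degree = max(deg),
       n_hubs = sum(hubs),
       provenance = prov)
}

#' Characteristic path length
#'
#' Mean number of edges in the shortest paths between pairs of nodes. For a
#' weighted graph, path lengths are sums of inverse weights (strong
#' connections are short). Disconnected graphs are handled according to
#' `disconnected`: averaging over reachable pairs only (default, with the
#' reachable fraction reported) or raising an error.
#'
#' @param g an igraph object with at least two nodes.
#' @param disconnected `"connected_pairs_only"` or `"error"`.
#' @return list with `L` (mean shortest path over ordered reachable pairs)
#'   and `reachable_pair_fraction`.
#' @examples
#' path_length(ring_lattice(10, 2))$L  # 25/9
#' @export
path_length <- function(g, disconnected = c("connected_pairs_only", "error")) {
  check_graph(g)
  disconnected <- match.arg(disconnected)
  n <- igraph::vcount(g)
  if (n < 2) stopf("path length needs at least 2 nodes")
  w <- if (is_weighted_graph(g)) 1 / igraph::E(g)$weight else NA
  D <- igraph::distances(g, weights = w,
                         mode = if (igraph::is_directed(g)) "out" else "all")
  d <- off_diagonal(D)
  reach <- is.finite(d)
  if (!any(reach)) stopf("graph has no reachable node pairs")
  if (disconnected == "error" && !all(reach)) {
    nc <- igraph::count_components(g)
    stopf("graph is disconnected (%d components)", nc)
  }
  list(L = mean(d[reach]), reachable_pair_fraction = mean(reach))
}

#' Average clustering coefficient
#'
#' Probability that two neighbors of a node are themselves connected,
#' averaged over nodes. Nodes of degree < 2 contribute 0 by default (so the
#' measure is defined for every graph); set `low_degree = "exclude"` to drop
#' them from the average instead. For weighted graphs the geometric-mean
#' triangle convention is used, with weights scaled by the largest weight.
#'
#' @param g an igraph object with at least 3 nodes.
#' @param low_degree treatment of nodes with fewer than two neighbors.
#' @return the clustering coefficient, in \[0, 1\].
#' @examples
#' clustering(ring_lattice(20, 4))  # 0.5
#' @export
clustering <- function(g, low_degree = c("zero", "exclude")) {
  check_graph(g)
  low_degree <- match.arg(low_degree)
  if (igraph::vcount(g) < 3) stopf("clustering needs at least 3 nodes")
  if (is_weighted_graph(g)) {
    ci <- weighted_local_clustering(g)
  } else {
    ci <- igraph::transitivity(g, type = "local", isolates = "NaN")
  }
  if (low_degree == "zero") ci[is.nan(ci)] <- 0 else ci <- ci[!is.nan(ci)]
  if (!length(ci)) stopf("no nodes of degree >= 2")
  mean(ci)
}

# Geometric-mean (Onnela) local clustering for weighted graphs.
weighted_local_clustering <- function(g) {
  W <- adjacency_of(g, weighted = TRUE)
  W <- W / max(W)
  W3 <- W^(1 / 3)
  num <- diag(W3 %*% W3 %*% W3)
  k <- rowSums(W > 0)
  ci <- ifelse(k >= 2, num / (k * (k - 1)), NaN)
  ci
}

#' Synchronizability and central point dominance
#'
#' Synchronizability is the Laplacian eigenratio
#' \eqn{\lambda_{max}/\lambda_2} of the combinatorial Laplacian; it is 1 for
#' the complete graph and grows as the graph becomes harder to synchronize.
#' Central point dominance (CPD) is Freeman's average difference between the
#' largest normalized betweenness and each node's normalized betweenness: 1
#' for a star, 0 for any vertex-transitive graph.
#'
#' @param g an undirected, connected igraph object (connectivity required for
#'   synchronizability).
#' @return list with `synchronizability` and `central_point_dominance`.
#' @export
spectral_and_centrality <- function(g) {
  check_graph(g, directed = FALSE)
  n <- igraph::vcount(g)
  if (n < 3) stopf("central point dominance needs at least 3 nodes")
  L <- igraph::laplacian_matrix(g, sparse = FALSE)
  ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  if (ev[2] < 1e-9) stopf("graph is disconnected (Laplacian lambda_2 = 0)")
  b <- igraph::betweenness(g, directed = FALSE) / ((n - 1) * (n - 2) / 2)
  list(synchronizability = ev[n] / ev[2],
       central_point_dominance = sum(max(b) - b) / (n - 1))
}

#' All standard measures of a graph
#'
#' Convenience wrapper returning average degree, path length, clustering and
#' (for undirected connected graphs) the spectral and centrality measures.
#'
#' @inheritParams degree_stats
#' @param spectral also compute synchronizability and CPD (undirected,
#'   connected graphs only).
#' @return a named list of measures with a `provenance` element.
#' @export
graph_measures <- function(g, hub_rule = "mean_plus_2sd", spectral = FALSE) {
  ds <- degree_stats(g, hub_rule)
  pl <- path_length(g)
  out <- list(average_degree = ds$average_degree,
              max_degree = ds$max_degree,
              n_hubs = ds$n_hubs,
              degree_distribution = ds$degree_distribution,
              L = pl$L,
              reachable_pair_fraction = pl$reachable_pair_fraction,
              C = clustering(g),
              provenance = ds$provenance)
  if (spectral) out <- c(out, spectral_and_centrality(g))
  out
}

#' Closed-form path length and clustering for canonical topologies
#'
#' Analytic (large-\eqn{N}) expressions for the characteristic path length
#' and clustering coefficient of the four canonical network models. These
#' make the size dependence explicit: for a ring lattice \eqn{L \approx
#' N/(2k)} grows linearly in \eqn{N} while \eqn{C = 3(k-2)/(4(k-1))} is
#' size-free; for an Erdos-Renyi graph \eqn{L \approx \ln N/\ln k} and
#' \eqn{C = k/N}; the Watts-Strogatz model interpolates through the
#' Newman-Moore-Watts scaling function for \eqn{L} and the Barrat-Weigt
#' factor \eqn{(1-p)^3} for \eqn{C}; the Barabasi-Albert model has
#' \eqn{L \approx \ln N/\ln\ln N} and \eqn{C \sim N^{-3/4}}.
#'
#' @param topology one of `"lattice"`, `"erdos_renyi"`, `"watts_strogatz"`,
#'   `"barabasi_albert"`.
#' @param N number of nodes.
#' @param k average degree (even and `N > 2k` for the lattice forms;
#'   `k > 1` for Erdos-Renyi).
#' @param p rewiring probability (Watts-Strogatz only).
#' @return list with `topology`, `parameters`, `L_closed_form`,
#'   `C_closed_form`.
#' @examples
#' analytic_measures("lattice", N = 200, k = 4)$C_closed_form  # 0.5
#' @export
analytic_measures <- function(topology = c("lattice", "erdos_renyi",
                                           "watts_strogatz",
                                           "barabasi_albert"),
                              N, k = NULL, p = NULL) {
  topology <- match.arg(topology)
  if (N <= 2) stopf("N must exceed 2")
  if (topology %in% c("lattice", "watts_strogatz")) {
    if (is.null(k) || k < 2) stopf("lattice forms need k >= 2")
    if (N <= 2 * k) stopf("lattice forms require N > 2k (got N=%g, k=%g)", N, k)
  }
  if (topology == "erdos_renyi" && (is.null(k) || k <= 1))
    stopf("Erdos-Renyi forms require k > 1")
  C_lat <- if (!is.null(k)) 3 * (k - 2) / (4 * (k - 1)) else NULL
  res <- switch(topology,
    lattice = list(L = N / (2 * k), C = C_lat),
    erdos_renyi = list(L = log(N) / log(k), C = k / N),
    watts_strogatz = {
      if (is.null(p) || p < 0 || p > 1) stopf("watts_strogatz needs p in [0,1]")
      u <- N * k * p / 2
      f <- if (u < 1e-12) 0.25 else
        atanh(sqrt(u / (u + 2))) / (2 * sqrt(u^2 + 2 * u))
      list(L = (2 * N / k) * f, C = C_lat * (1 - p)^3)
    },
    barabasi_albert = list(L = log(N) / log(log(N)), C = N^(-0.75)))
  list(topology = topology,
       parameters = list(N = N, k = k, p = p),
       L_closed_form = res$L, C_closed_form = res$C)
}
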