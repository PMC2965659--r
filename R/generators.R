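#' Ring lattice
#'
#' Circulant graph in which every node is connected to its `k/2` nearest
#' neighbors on each side. The regular starting point of the Watts-Strogatz
#' model; its clustering coefficient `3(k-2)/(4(k-1))` does not depend on
#' the number of nodes.
#'
#' @param N number of nodes (`N >= k + 1`).
#' @param k degree, even.
#' @return an undirected igraph object, regular of degree `k`.
#' @examples
#' clustering(ring_lattice(20, 4))
#' @export
ring_lattice <- function(N, k) {
  if (k %% 2 != 0) stopf("ring lattice requires an even k (got %g)", k)
  if (k < 2 || N < k + 1) stopf("ring lattice requires N >= k + 1 >= 3")
  from <- rep(seq_len(N), k / 2)
  d <- rep(seq_len(k / 2), each = N)
  to <- ((from - 1 + d) %% N) + 1
  g <- igraph::make_empty_graph(N, directed = FALSE)
  igraph::add_edges(g, rbind(from, to))
}

# Deterministic "nearest-integer" lattice with exactly E edges: fill whole
# distance rings first, then spread the remaining edges round-robin around
# the ring. Used for fixed-density sweeps and as the lattice reference in
# range normalization, where E need not equal N*k/2 for an even k.
nearest_lattice <- function(N, E) {
  if (E > N * (N - 1) / 2) stopf("E exceeds the number of possible edges")
  from <- integer(0); to <- integer(0)
  left <- E
  d <- 1
  while (left > 0) {
    ring_size <- if (2 * d == N) N / 2 else N
    idx <- if (left >= ring_size) seq_len(ring_size) - 1L
           else floor((seq_len(left) - 1) * N / left)
    from <- c(from, idx + 1L)
    to <- c(to, ((idx + d) %% N) + 1L)
    left <- left - length(idx)
    d <- d + 1
  }
  g <- igraph::make_empty_graph(N, directed = FALSE)
  igraph::add_edges(g, rbind(from, to))
}

#' Erdos-Renyi random graph with a target average degree
#'
#' Each of the `N(N-1)/2` undirected pairs is an edge independently with
#' probability `k/(N-1)`, so the ensemble mean degree is `k`.
#'
#' @param N number of nodes.
#' @param k target average degree in `[0, N-1]`.
#' @param seed optional RNG seed.
#' @return an undirected igraph object.
#' @export
erdos_renyi <- function(N, k, seed = NULL) {
  if (k < 0 || k > N - 1) stopf("k must lie in [0, N-1]")
  with_seed(seed, igraph::sample_gnp(N, k / (N - 1)))
}

#' Watts-Strogatz small-world graph
#'
#' Starts from `ring_lattice(N, k)` and rewires each edge independently with
#' probability `p`, redrawing the far endpoint uniformly among nodes that
#' create neither a self-loop nor a duplicate edge. Edges carry a logical
#' `rewired` attribute distinguishing long-range from local connections:
#' with `N = 100`, `k = 10`, `p = 0.1` the expected split is 900 local and
#' 100 long-range connection stubs.
#'
#' @inheritParams ring_lattice
#' @param p rewiring probability in `[0, 1]`.
#' @param seed optional RNG seed.
#' @return an undirected igraph object with edge attribute `rewired`.
#' @export
watts_strogatz <- function(N, k, p, seed = NULL) {
  if (p < 0 || p > 1) stopf("p must lie in [0, 1]")
  g <- ring_lattice(N, k)
  with_seed(seed, rewire_ws(g, p))
}

# Rewire the far endpoint of each edge with probability p; edges gain a
# logical attribute `rewired`. Weights, if present, travel with the edge.
rewire_ws <- function(g, p) {
  N <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- if (is_weighted_graph(g)) igraph::E(g)$weight else NULL
  adj <- lapply(seq_len(N), function(i) integer(0))
  for (e in seq_len(nrow(el))) {
    adj[[el[e, 1]]] <- c(adj[[el[e, 1]]], el[e, 2])
    adj[[el[e, 2]]] <- c(adj[[el[e, 2]]], el[e, 1])
  }
  do_rewire <- runif(nrow(el)) < p
  rewired <- logical(nrow(el))
  for (e in which(do_rewire)) {
    i <- el[e, 1]; j <- el[e, 2]
    free <- setdiff(seq_len(N), c(i, adj[[i]]))
    if (!length(free)) next  # near-complete: no valid target, keep edge
    jn <- if (length(free) == 1) free else sample(free, 1)
    adj[[i]] <- c(setdiff(adj[[i]], j), jn)
    adj[[j]] <- setdiff(adj[[j]], i)
    adj[[jn]] <- c(adj[[jn]], i)
    el[e, 2] <- jn
    rewired[e] <- TRUE
  }
  out <- igraph::make_empty_graph(N, directed = FALSE)
  out <- igraph::add_edges(out, t(el))
  igraph::E(out)$rewired <- rewired
  if (!is.null(w)) igraph::E(out)$weight <- w
  out
}

#' Watts-Strogatz graph at an exact edge density
#'
#' Variant of [watts_strogatz()] for fixed-density sweeps where the implied
#' average degree `density * (N - 1)` is not an even integer: starts from a
#' nearest-integer ring lattice with exactly `round(density * N(N-1)/2)`
#' edges (whole nearest-neighbor rings first, leftovers spread evenly) and
#' rewires each edge with probability `p`.
#'
#' @param N number of nodes.
#' @param density target edge density in (0, 1\].
#' @param p rewiring probability.
#' @param seed optional RNG seed.
#' @return an undirected igraph object with edge attribute `rewired`.
#' @export
watts_strogatz_density <- function(N, density, p, seed = NULL) {
  if (density <= 0 || density > 1) stopf("density must lie in (0, 1]")
  if (p < 0 || p > 1) stopf("p must lie in [0, 1]")
  g <- nearest_lattice(N, round(density * N * (N - 1) / 2))
  with_seed(seed, rewire_ws(g, p))
}

#' Barabasi-Albert preferential-attachment graph
#'
#' Growth model: starting from `m` unconnected seed nodes, every new node
#' attaches to `m` distinct existing nodes with probability proportional to
#' their degree (the first arrival connects to all seeds). The result is
#' connected with exactly `m(N - m)` edges and a heavy-tailed degree
#' distribution.
#'
#' @param N number of nodes (`N > m`).
#' @param m edges added per new node (`m >= 1`).
#' @param seed optional RNG seed.
#' @return an undirected igraph object.
#' @export
barabasi_albert <- function(N, m, seed = NULL) {
  if (m < 1 || N <= m) stopf("requires N > m >= 1")
  with_seed(seed, {
    from <- integer(0); to <- integer(0)
    # stub multiset for preferential attachment (node listed once per degree)
    stubs <- integer(0)
    first <- m + 1L
    from <- c(from, rep(first, m)); to <- c(to, seq_len(m))
    stubs <- c(rep(first, m), seq_len(m))
    if (N > first) for (t in (first + 1L):N) {
      targets <- integer(0)
      while (length(targets) < m) {
        cand <- stubs[sample.int(length(stubs), 1)]
        if (!(cand %in% targets)) targets <- c(targets, cand)
      }
      from <- c(from, rep(t, m)); to <- c(to, targets)
      stubs <- c(stubs, rep(t, m), targets)
    }
    g <- igraph::make_empty_graph(N, directed = FALSE)
    igraph::add_edges(g, rbind(from, to))
  })
}

#' Degree-preserving randomization (Maslov-Sneppen rewiring)
#'
#' Repeated double-edge swaps that keep every node's degree fixed while
#' destroying all other structure. Used to build random surrogates with the
#' same degree distribution as the original network.
#'
#' @param g an unweighted igraph object.
#' @param n_swaps number of attempted swaps; default `10 * ecount(g)`.
#' @param seed optional RNG seed.
#' @return a graph with the identical degree sequence. If no swap is
#'   possible (e.g. a complete graph) the input is returned with a warning
#'   and graph attribute `no_swap_possible`.
#' @export
rewire_preserving_degrees <- function(g, n_swaps = NULL, seed = NULL) {
  check_graph(g, weighted = FALSE)
  n_swaps <- n_swaps %||% (10 * igraph::ecount(g))
  if (n_swaps < 1) stopf("n_swaps must be >= 1")
  N <- igraph::vcount(g)
  if (igraph::ecount(g) == N * (N - 1) / 2 && !igraph::is_directed(g)) {
    warnf("complete graph admits no degree-preserving swap; returning input")
    return(igraph::set_graph_attr(g, "no_swap_possible", TRUE))
  }
  out <- with_seed(seed,
    igraph::rewire(g, igraph::keeping_degseq(loops = FALSE, niter = n_swaps)))
  out
}

#' Weighted ring lattice with subsequent rewiring
#'
#' Emulates a weighted small-world network carrying a prescribed multiset of
#' connection weights: the weights are placed uniformly at random on the
#' edge slots of a nearest-integer ring lattice (whole nearest-neighbor
#' rings first, leftover slots spread evenly), after which each edge is
#' rewired with probability `p`, carrying its weight along. Used to build
#' baseline models for weighted empirical networks.
#'
#' @param weights vector of nonnegative edge weights (length `W` determines
#'   the density, `k ~ 2W/N`).
#' @param N number of nodes.
#' @param p rewiring probability.
#' @param seed optional RNG seed.
#' @return a weighted undirected igraph object with edge attribute
#'   `rewired`.
#' @export
lattice_with_weights <- function(weights, N, p, seed = NULL) {
  W <- length(weights)
  if (W > N * (N - 1) / 2) stopf("more weights than possible edges")
  if (any(weights < 0)) stopf("weights must be nonnegative")
  if (p < 0 || p > 1) stopf("p must lie in [0, 1]")
  g <- nearest_lattice(N, W)
  with_seed(seed, {
    igraph::E(g)$weight <- sample(weights)
    rewire_ws(g, p)
  })
}
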