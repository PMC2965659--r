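#' Synthetic connectivity matrix with a planted topology
#'
#' Emulates a sensor-level functional connectivity matrix (e.g. phase
#' uniformity between all sensor pairs): a planted network topology
#' contributes `base_strength` to the connectivity of its edges, a
#' `global_offset` shifts the overall connectivity level (emulating
#' between-condition differences in total connectivity), and additive
#' Gaussian noise with SD `noise_sd` is applied symmetrically. Values are
#' clipped to `[0, 1]` and the diagonal is zero. With
#' `base_strength >= 5 * noise_sd` the planted edges are recoverable by
#' thresholding at the planted density.
#'
#' @param planted_topology a [generator_spec()] for the planted graph.
#' @param base_strength connectivity added on planted edges, in (0, 1).
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param global_offset baseline connectivity added everywhere.
#' @param seed optional RNG seed.
#' @return list with `cm` (a [connectivity_matrix()]) and `planted` (the
#'   planted igraph), plus the generating parameters.
#' @export
synth_connectivity <- function(planted_topology, base_strength = 0.5,
                               noise_sd = 0.05, global_offset = 0.1,
                               seed = NULL) {
  stopifnot(inherits(planted_topology, "generator_spec"))
  if (base_strength <= 0 || base_strength >= 1)
    stopf("base_strength must lie in (0, 1)")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  with_seed(seed, {
    g <- generate_graph(planted_topology)
    N <- igraph::vcount(g)
    A <- adjacency_of(g)
    noise <- matrix(0, N, N)
    noise[upper.tri(noise)] <- rnorm(N * (N - 1) / 2, 0, noise_sd)
    noise <- noise + t(noise)
    V <- base_strength * A + global_offset + noise
    V <- pmin(pmax(V, 0), 1)
    diag(V) <- 0
    list(cm = connectivity_matrix(V), planted = g,
         base_strength = base_strength, noise_sd = noise_sd,
         global_offset = global_offset, seed = seed)
  })
}
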