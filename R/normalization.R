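# Surrogate- and range-based normalization of L and C, and the small-world
# index. The central caveat these functions expose: dividing by a random
# reference does not remove the N,k-dependence of a measure, and for C it
# introduces one where the raw value had none.

measure_value <- function(g, measure) {
  switch(measure,
         L = path_length(g)$L,
         C = clustering(g),
         stopf("unknown measure '%s'", measure))
}

# Draw one surrogate matched to g's N and E (and degree sequence when
# ensemble = "degree_preserving").
draw_surrogate <- function(g, ensemble) {
  if (ensemble == "erdos_renyi") {
    igraph::sample_gnm(igraph::vcount(g), igraph::ecount(g))
  } else {
    suppressWarnings(rewire_preserving_degrees(g))
  }
}

surrogate_measures <- function(g, measures, ensemble, n_surrogates, seed,
                               retry_cap = 10) {
  check_graph(g, weighted = FALSE)
  if (igraph::vcount(g) < 4) stopf("need at least 4 nodes")
  if (n_surrogates < 1) stopf("n_surrogates must be >= 1")
  with_seed(seed, {
    out <- matrix(NA_real_, n_surrogates, length(measures),
                  dimnames = list(NULL, measures))
    for (r in seq_len(n_surrogates)) {
      for (try in seq_len(retry_cap)) {
        s <- draw_surrogate(g, ensemble)
        v <- tryCatch(vapply(measures, measure_value, numeric(1), g = s),
                      error = function(e) NULL)
        if (!is.null(v) && all(is.finite(v))) { out[r, ] <- v; break }
      }
      if (anyNA(out[r, ]))
        stopf("measure undefined on %d consecutive surrogates", retry_cap)
    }
    out
  })
}

#' Normalize a graph measure by random surrogates
#'
#' Divides the observed path length or clustering coefficient by its mean
#' over random surrogates matched in the number of nodes and edges
#' (`ensemble = "erdos_renyi"`) or additionally in the full degree sequence
#' (`"degree_preserving"`, Maslov-Sneppen rewiring). Note that the
#' normalized value generally still depends on `N` and `k`; see
#' [range_normalize()] for an alternative.
#'
#' @param g an unweighted igraph object with at least 4 nodes.
#' @param measure `"L"` or `"C"`.
#' @param ensemble surrogate ensemble.
#' @param n_surrogates number of surrogate draws (default 200).
#' @param seed optional RNG seed.
#' @return list with `raw`, `reference_mean`, `reference_sd`, `normalized`
#'   (= raw / reference_mean), `ensemble`, `n_surrogates`, `seed`.
#' @export
surrogate_normalize <- function(g, measure = c("L", "C"),
                                ensemble = c("erdos_renyi",
                                             "degree_preserving"),
                                n_surrogates = 200, seed = NULL) {
  measure <- match.arg(measure)
  ensemble <- match.arg(ensemble)
  raw <- measure_value(g, measure)
  ref <- surrogate_measures(g, measure, ensemble, n_surrogates, seed)[, 1]
  list(raw = raw, reference_mean = mean(ref), reference_sd = stats::sd(ref),
       normalized = raw / mean(ref), ensemble = ensemble,
       n_surrogates = n_surrogates, seed = seed)
}

#' Small-world index
#'
#' `SW = (C/C_rand) / (L/L_rand)`, with both normalizations taken from the
#' same surrogate draws. Values well above 1 indicate small-world structure
#' (lattice-like clustering with random-like path length) -- but the index
#' grows with network size even at a fixed topology, so absolute SW values
#' of networks with different `N` or `k` are not comparable.
#'
#' @inheritParams surrogate_normalize
#' @return list with `raw` (named `C`, `L`), reference means/sds,
#'   `normalized_C`, `normalized_L`, `sw`, `ensemble`, `n_surrogates`,
#'   `seed`.
#' @export
small_world_index <- function(g, ensemble = c("erdos_renyi",
                                              "degree_preserving"),
                              n_surrogates = 200, seed = NULL) {
  ensemble <- match.arg(ensemble)
  raw <- c(C = clustering(g), L = path_length(g)$L)
  ref <- surrogate_measures(g, c("C", "L"), ensemble, n_surrogates, seed)
  nC <- raw["C"] / mean(ref[, "C"])
  nL <- raw["L"] / mean(ref[, "L"])
  list(raw = raw,
       reference_mean = colMeans(ref),
       reference_sd = apply(ref, 2, stats::sd),
       normalized_C = unname(nC), normalized_L = unname(nL),
       sw = unname(nC / nL),
       ensemble = ensemble, n_surrogates = n_surrogates, seed = seed)
}

#' Normalize a measure by its range of obtainable values
#'
#' Expresses the observed path length or clustering as a fraction of the
#' range spanned by a ring lattice (upper end) and a random network (lower
#' end) matched to the graph's `N` and `E`:
#' `(raw - mean_random) / (lattice - mean_random)`. For networks with
#' small-world structure this is markedly less sensitive to `N` and `k`
#' than division by the random reference alone.
#'
#' @inheritParams surrogate_normalize
#' @return list with `raw`, `reference_mean` (random), `reference_sd`,
#'   `lattice_value`, `normalized`, `n_surrogates`, `seed`.
#' @export
range_normalize <- function(g, measure = c("L", "C"), n_surrogates = 200,
                            seed = NULL) {
  measure <- match.arg(measure)
  raw <- measure_value(g, measure)
  ref <- surrogate_measures(g, measure, "erdos_renyi", n_surrogates, seed)[, 1]
  lat <- measure_value(nearest_lattice(igraph::vcount(g), igraph::ecount(g)),
                       measure)
  rand_mean <- mean(ref)
  if (abs(lat - rand_mean) < 1e-9)
    stopf("degenerate range: lattice and random references coincide")
  list(raw = raw, reference_mean = rand_mean,
       reference_sd = stats::sd(ref), lattice_value = lat,
       normalized = (raw - rand_mean) / (lat - rand_mean),
       ensemble = "lattice_random_range",
       n_surrogates = n_surrogates, seed = seed)
}
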