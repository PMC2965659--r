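#' Connectivity matrix
#'
#' Wraps a square symmetric matrix of connectivity values (e.g. coherence or
#' phase uniformity between sensor pairs) before conversion to a graph. The
#' diagonal is ignored and set to zero; entries must be finite and the
#' matrix symmetric within `1e-9`.
#'
#' @param values square numeric matrix.
#' @param node_labels optional character vector of node names.
#' @return an object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(values, node_labels = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stopf("connectivity matrix must be square")
  if (any(!is.finite(values))) stopf("connectivity matrix has non-finite entries")
  if (max(abs(values - t(values))) > 1e-9)
    stopf("connectivity matrix is not symmetric (tolerance 1e-9)")
  diag(values) <- 0
  if (!is.null(node_labels)) {
    stopifnot(length(node_labels) == nrow(values))
    dimnames(values) <- list(node_labels, node_labels)
  }
  structure(list(values = values, node_labels = node_labels),
            class = "connectivity_matrix")
}

#' @export
as.matrix.connectivity_matrix <- function(x, ...) x$values

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("connectivity matrix: %d nodes, values in [%.3g, %.3g]\n",
              nrow(x$values), min(off_diagonal(x$values)),
              max(off_diagonal(x$values))))
  invisible(x)
}

#' Binarize a connectivity matrix into an unweighted graph
#'
#' The three common thresholding regimes: a *fixed threshold* keeps every
#' pair whose connectivity exceeds `value`; a *fixed average degree* keeps
#' the `round(N k / 2)` strongest pairs; a *fixed edge density* keeps the
#' `round(value * N(N-1)/2)` strongest pairs. For networks with equal `N`
#' the last two coincide. Ties at the cut value are broken by descending
#' connectivity and then lexicographic node-pair order, and counted in the
#' report.
#'
#' @param cm a [connectivity_matrix()] (or square symmetric matrix).
#' @param mode one of `"fixed_threshold"`, `"fixed_degree"`,
#'   `"fixed_density"`.
#' @param value threshold tau, target average degree k, or target density.
#' @param strict for `fixed_threshold`, keep pairs with connectivity
#'   strictly above tau (default) or at-or-above.
#' @return list with `graph` (undirected igraph) and `report` (mode,
#'   threshold_used, achieved_k, achieved_density, n_ties_broken).
#' @examples
#' cm <- connectivity_matrix(matrix(c(0, .9, .8, .1,
#'                                    .9, 0, .7, .3,
#'                                    .8, .7, 0, .2,
#'                                    .1, .3, .2, 0), 4, 4))
#' binarize(cm, "fixed_density", 0.5)$report
#' @export
binarize <- function(cm, mode = c("fixed_threshold", "fixed_degree",
                                  "fixed_density"),
                     value, strict = TRUE) {
  if (!inherits(cm, "connectivity_matrix")) cm <- connectivity_matrix(cm)
  mode <- match.arg(mode)
  V <- cm$values
  N <- nrow(V)
  ut <- which(upper.tri(V), arr.ind = TRUE)
  vals <- V[ut]
  n_pairs <- nrow(ut)
  ties <- 0L
  if (mode == "fixed_threshold") {
    keep <- if (strict) vals > value else vals >= value
    thr <- value
  } else {
    target_E <- if (mode == "fixed_degree") round(N * value / 2)
                else round(value * n_pairs)
    if (target_E > sum(vals > 0))
      stopf("target of %d edges exceeds the %d nonzero pairs available",
            target_E, sum(vals > 0))
    ord <- order(-vals, ut[, 1], ut[, 2])
    keep <- logical(n_pairs)
    keep[ord[seq_len(target_E)]] <- TRUE
    thr <- if (target_E > 0) vals[ord[target_E]] else Inf
    if (target_E > 0) {
      at_cut <- sum(vals == thr)
      kept_at_cut <- sum(keep & vals == thr)
      if (kept_at_cut < at_cut) ties <- at_cut
    }
  }
  el <- ut[keep, , drop = FALSE]
  g <- igraph::make_empty_graph(N, directed = FALSE)
  g <- igraph::add_edges(g, t(el))
  if (!is.null(cm$node_labels)) igraph::V(g)$name <- cm$node_labels
  E <- sum(keep)
  list(graph = g,
       report = list(mode = mode, threshold_used = thr,
                     achieved_k = 2 * E / N,
                     achieved_density = E / n_pairs,
                     n_ties_broken = ties))
}

#' Weighted graph from a connectivity matrix
#'
#' Keeps the connectivity values as edge weights instead of binarizing; the
#' graph then consists of zeros and weights rather than zeros and ones.
#' Optionally zeroes all entries at or below a significance threshold.
#'
#' @inheritParams binarize
#' @param significance_tau optional threshold; entries `<= significance_tau`
#'   are removed.
#' @return a weighted undirected igraph object.
#' @export
weighted_graph <- function(cm, significance_tau = NULL) {
  if (!inherits(cm, "connectivity_matrix")) cm <- connectivity_matrix(cm)
  V <- cm$values
  if (any(off_diagonal(V) < 0)) stopf("weights must be nonnegative")
  if (!is.null(significance_tau)) V[V <= significance_tau] <- 0
  graph_from_adjacency(V, directed = FALSE, weighted = TRUE)
}
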