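# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state; seed = NULL means "use the current stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Spawn reproducible sub-seeds from one master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Validate a graph argument and (optionally) its directedness/weights.
check_graph <- function(g, directed = NULL, weighted = NULL,
                        arg = deparse(substitute(g))) {
  if (!igraph::is_igraph(g)) stopf("`%s` must be an igraph object", arg)
  if (igraph::vcount(g) == 0) stopf("`%s` has no nodes", arg)
  if (any(igraph::which_loop(g))) stopf("`%s` contains self-loops", arg)
  if (!is.null(directed) && igraph::is_directed(g) != directed)
    stopf("`%s` must be %s", arg, if (directed) "directed" else "undirected")
  if (!is.null(weighted)) {
    has_w <- is_weighted_graph(g)
    if (weighted && !has_w) stopf("`%s` must be weighted", arg)
    if (!weighted && has_w)
      stopf("`%s` must be unweighted (binary)", arg)
  }
  invisible(g)
}

is_weighted_graph <- function(g) "weight" %in% igraph::edge_attr_names(g)

# Dense 0/1 (or weight) adjacency matrix of a graph.
adjacency_of <- function(g, weighted = NULL) {
  w <- if (isTRUE(weighted) ||
           (is.null(weighted) && is_weighted_graph(g))) "weight" else NULL
  as.matrix(igraph::as_adjacency_matrix(g, attr = w, sparse = FALSE))
}

graph_from_adjacency <- function(A, directed = FALSE, weighted = FALSE) {
  mode <- if (directed) "directed" else "undirected"
  igraph::graph_from_adjacency_matrix(A, mode = mode,
                                      weighted = if (weighted) TRUE else NULL,
                                      diag = FALSE)
}

off_diagonal <- function(A) A[row(A) != col(A)]
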