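# Reading and writing square adjacency / connectivity matrices and graphs.

read_square_matrix <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- tryCatch(read.table(path, sep = sep, header = FALSE,
                             stringsAsFactors = FALSE, comment.char = ""),
                  error = function(e) stopf("cannot parse '%s': %s",
                                            path, conditionMessage(e)))
  labels <- NULL
  is_text <- function(x) {  # non-numeric strings; "NaN" stays numeric
    v <- suppressWarnings(as.numeric(x))
    any(is.na(v) & !is.nan(v))
  }
  if (is_text(unlist(raw[1, ]))) {  # header row (maybe with a label column)
    labels <- as.character(unlist(raw[1, ]))
    raw <- raw[-1, , drop = FALSE]
    if (is_text(raw[[1]])) {
      raw <- raw[, -1, drop = FALSE]
      labels <- labels[-1]
    }
  }
  M <- suppressWarnings(apply(as.matrix(raw), c(1, 2), as.numeric))
  if (anyNA(M)) stopf("'%s' contains non-numeric or NaN entries", path)
  if (nrow(M) != ncol(M))
    stopf("'%s' is not square (%d x %d)", path, nrow(M), ncol(M))
  dimnames(M) <- if (!is.null(labels)) list(labels, labels) else NULL
  M
}

#' Read a graph or connectivity matrix from a CSV/TSV square matrix
#'
#' Field separator is inferred from the file extension (`.csv` comma,
#' otherwise tab); an optional header row/column of labels is detected.
#'
#' @param path file path.
#' @param directed expected directedness (undirected input must be
#'   symmetric).
#' @param weighted read entries as weights instead of 0/1 indicators.
#' @param as return a `"graph"` (igraph) or a `"connectivity"` matrix.
#' @return an igraph object or a [connectivity_matrix()].
#' @export
read_adjacency <- function(path, directed = FALSE, weighted = FALSE,
                           as = c("graph", "connectivity")) {
  as <- match.arg(as)
  M <- read_square_matrix(path)
  if (!directed && max(abs(M - t(M))) > 1e-9)
    stopf("'%s' is asymmetric but directed = FALSE", path)
  if (as == "connectivity")
    return(connectivity_matrix(M, node_labels = rownames(M)))
  if (any(diag(M) != 0)) stopf("'%s' has nonzero diagonal entries", path)
  if (!weighted && !all(M %in% c(0, 1)))
    stopf("'%s' has non-binary entries but weighted = FALSE", path)
  g <- graph_from_adjacency(M, directed = directed, weighted = weighted)
  if (!is.null(rownames(M))) igraph::V(g)$name <- rownames(M)
  g
}

#' Write a graph to disk
#'
#' Formats: `csv_matrix` (square adjacency/weight matrix), `edge_list`
#' (tab-separated `source target weight`, 0-based node ids, sorted), or
#' `graphml`.
#'
#' @param g an igraph object.
#' @param path output path.
#' @param format output format.
#' @return the path, invisibly.
#' @export
write_graph_file <- function(g, path, format = c("csv_matrix", "edge_list",
                                                 "graphml")) {
  check_graph(g)
  format <- match.arg(format)
  if (format == "csv_matrix") {
    A <- adjacency_of(g)
    write.table(A, path, sep = ",", row.names = FALSE, col.names = FALSE)
  } else if (format == "edge_list") {
    el <- igraph::as_edgelist(g, names = FALSE) - 1
    w <- if (is_weighted_graph(g)) igraph::E(g)$weight else rep(1, nrow(el))
    o <- order(el[, 1], el[, 2])
    write.table(data.frame(el[o, 1], el[o, 2], w[o]), path, sep = "\t",
                row.names = FALSE, col.names = FALSE)
  } else {
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Write a set of graph measures as tidy CSV
#'
#' @param measures a named list as returned by [graph_measures()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_measures <- function(measures, path) {
  keep <- vapply(measures, function(x) is.numeric(x) && length(x) == 1,
                 logical(1))
  df <- data.frame(measure = names(measures)[keep],
                   value = unlist(measures[keep], use.names = FALSE),
                   provenance = as.character(
                     jsonlite::toJSON(measures$provenance, auto_unbox = TRUE,
                                      force = TRUE)))
  write.table(df, path, sep = ",", row.names = FALSE)
  invisible(path)
}
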