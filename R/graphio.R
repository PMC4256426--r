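# Graph loading, validation, and descriptive statistics.
#
# Graphs are plain undirected igraph objects: simple (no loops, no multi
# edges), vertices 1..n, with the original input labels kept in the `name`
# vertex attribute. All readers funnel through validate_graph() so every
# downstream module can assume a clean simple graph.

#' Validate an undirected simple graph
#'
#' Checks the structural invariants every `tiegame` function relies on:
#' undirected, no self-loops, no duplicate edges, and the degree sum equal to
#' twice the edge count.
#'
#' @param g An [igraph][igraph::graph] object.
#' @return `g`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_graph <- function(g) {
  if (!igraph::is_igraph(g)) abort("`g` must be an igraph object")
  if (igraph::is_directed(g)) abort("`g` must be undirected")
  if (any(igraph::which_loop(g))) abort("`g` must not contain self-loops")
  if (any(igraph::which_multiple(g))) abort("`g` must not contain duplicate edges")
  stopifnot(sum(igraph::degree(g)) == 2L * igraph::ecount(g))
  invisible(g)
}

#' Read an undirected graph from a whitespace-separated edge list
#'
#' Each non-comment line must hold two integer vertex labels. Duplicate
#' lines, reversed duplicates, and self-loops are collapsed or dropped (with
#' a warning for self-loops); vertex labels are remapped to contiguous ids
#' `1..n` in increasing label order, the original labels being retained in
#' the `name` vertex attribute.
#'
#' @param path Path to the edge-list file. Lines starting with `#` are
#'   skipped; fields may be separated by spaces or tabs.
#' @param one_based If `TRUE`, input labels are documented as starting at 1
#'   (purely informational: labels are remapped to contiguous ids either way).
#' @return A validated undirected simple [igraph][igraph::graph] object.
#' @export
read_edge_list <- function(path, one_based = FALSE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) abort(paste0("empty edge list: ", path))
  toks <- strsplit(trimws(lines[idx]), "[ \t]+")
  bad <- which(vapply(toks, length, 1L) != 2L)
  if (length(bad) > 0L) {
    abort(sprintf("malformed edge-list line %d in %s: %s",
                  idx[bad[1]], path, lines[idx[bad[1]]]))
  }
  m <- matrix(suppressWarnings(as.integer(unlist(toks))), ncol = 2, byrow = TRUE)
  if (anyNA(m)) {
    bad <- idx[which(rowSums(is.na(m)) > 0)[1]]
    abort(sprintf("malformed edge-list line %d in %s: non-integer token", bad, path))
  }
  loops <- m[, 1] == m[, 2]
  if (any(loops)) {
    warn(sprintf("dropped %d self-loop(s) in %s", sum(loops), path))
    m <- m[!loops, , drop = FALSE]
  }
  if (nrow(m) == 0L) abort(paste0("no edges after removing self-loops: ", path))
  labels <- sort(unique(as.vector(m)))
  ids <- matrix(match(m, labels), ncol = 2)
  # collapse duplicates and reversed duplicates
  key <- paste(pmin(ids[, 1], ids[, 2]), pmax(ids[, 1], ids[, 2]))
  ids <- ids[!duplicated(key), , drop = FALSE]
  g <- igraph::graph_from_edgelist(ids, directed = FALSE)
  igraph::V(g)$name <- as.character(labels)
  validate_graph(g)
  g
}

#' Read an undirected graph from a 0/1 adjacency matrix file
#'
#' Accepts either a dense whitespace-separated text matrix or a MatrixMarket
#' (`.mtx`) sparse matrix. The matrix is symmetrized by OR-ing with its
#' transpose (with a warning if it was asymmetric); the diagonal is ignored;
#' isolated vertices are dropped, their count reported, so that only
#' connected vertices remain.
#'
#' @param path Path to the matrix file.
#' @return A validated undirected simple [igraph][igraph::graph] object.
#' @export
read_adjacency_matrix <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    a <- methods::as(Matrix::readMM(path), "CsparseMatrix")
  } else {
    rows <- readLines(path, warn = FALSE)
    rows <- rows[!grepl("^\\s*(#|$)", rows)]
    vals <- lapply(strsplit(trimws(rows), "[ \t,]+"), as.numeric)
    ncols <- unique(vapply(vals, length, 1L))
    if (length(ncols) != 1L) abort("ragged adjacency matrix: unequal row lengths")
    a <- Matrix::Matrix(do.call(rbind, vals), sparse = TRUE)
  }
  if (nrow(a) != ncol(a)) {
    abort(sprintf("adjacency matrix must be square, got %d x %d", nrow(a), ncol(a)))
  }
  a <- (a != 0) * 1
  if (!Matrix::isSymmetric(a)) {
    warn("asymmetric adjacency matrix: symmetrized by OR with transpose")
    a <- ((a + Matrix::t(a)) != 0) * 1
  }
  Matrix::diag(a) <- 0
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected", diag = FALSE)
  igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  iso <- which(igraph::degree(g) == 0)
  if (length(iso) > 0L) {
    inform(sprintf("dropped %d isolated vertex/vertices", length(iso)))
    g <- igraph::delete_vertices(g, iso)
  }
  if (igraph::vcount(g) == 0L) abort("adjacency matrix has no edges")
  validate_graph(g)
  g
}

#' Descriptive statistics of a graph
#'
#' One-row summary of the network: size, density, mean degree (both the
#' `2E/N` and `E/N` conventions), diameter and mean shortest-path length
#' (computed on the largest connected component), and the average local
#' clustering coefficient (vertices of degree < 2 contribute 0).
#'
#' @param g An undirected simple [igraph][igraph::graph] object.
#' @return A one-row tibble with columns `n_nodes`, `n_edges`, `mean_degree`,
#'   `edge_node_ratio`, `density`, `diameter`, `mean_path_length`,
#'   `clustering`.
#' @export
graph_stats <- function(g) {
  validate_graph(g)
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  if (n == 0L) abort("empty graph")
  comp <- igraph::components(g)
  lcc <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
  cc <- igraph::transitivity(g, type = "localaverageundirected", isolates = "zero")
  tibble(
    n_nodes = n,
    n_edges = e,
    mean_degree = 2 * e / n,
    edge_node_ratio = e / n,
    density = if (n > 1) 2 * e / (n * (n - 1)) else 0,
    diameter = igraph::diameter(lcc, unconnected = FALSE),
    mean_path_length = igraph::mean_distance(lcc),
    clustering = if (is.nan(cc)) 0 else cc
  )
}

#' Write graph statistics to TSV or JSON
#'
#' @param stats A one-row tibble from [graph_stats()].
#' @param path Output file; format chosen by extension (`.json` or anything
#'   else for tab-separated).
#' @return `path`, invisibly.
#' @export
write_graph_stats <- function(stats, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.list(stats), path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write a graph as a whitespace-separated edge list
#'
#' @param g An undirected simple graph.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  validate_graph(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  utils::write.table(el, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
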