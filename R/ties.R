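# Tie strengths from neighborhood overlap.
#
# The strength of an edge (i, j) is the topological overlap
#     w_ij = n_ij / ((k_i - 1) + (k_j - 1) - n_ij)
# where n_ij is the number of common neighbors and k the degrees: the
# fraction of the two players' other relations that they share. Connected
# pairs with no common neighbors are not given zero (they do have a
# friendship) but a positive floor value, so that w_ij is always in (0, 1].

#' Topological overlap of a single edge
#'
#' The raw (pre-floor) overlap of an existing edge: the number of common
#' neighbors divided by the number of distinct other neighbors of the two
#' endpoints. Returns 0 when the endpoints share no neighbors (the floor is
#' applied later by [compute_ties()]).
#'
#' @param g An undirected simple graph.
#' @param i,j Vertex ids (1-based) of an edge of `g`.
#' @param method `"overlap"` for the topological overlap (default), or
#'   `"jaccard"` for plain Jaccard similarity of the full neighbor sets, as a
#'   sensitivity alternative.
#' @return A number in `[0, 1]`.
#' @export
tie_overlap <- function(g, i, j, method = c("overlap", "jaccard")) {
  method <- rlang::arg_match(method)
  eid <- igraph::get_edge_ids(g, c(i, j), error = FALSE)
  if (eid == 0L) abort(sprintf("(%s, %s) is not an edge of the graph", i, j))
  ni <- igraph::neighbors(g, i)
  nj <- igraph::neighbors(g, j)
  n_common <- length(intersect(as.integer(ni), as.integer(nj)))
  overlap_value(n_common, length(ni), length(nj), method)
}

overlap_value <- function(n_common, k_i, k_j, method = "overlap") {
  denom <- if (method == "jaccard") k_i + k_j - n_common
           else (k_i - 1) + (k_j - 1) - n_common
  ifelse(n_common == 0, 0, n_common / denom)
}

#' Compute tie strengths for every edge of a graph
#'
#' Assigns every edge its neighborhood-overlap strength, then raises
#' zero-overlap edges to a strictly positive floor. Under the default
#' `"min_positive"` policy the floor is the smallest positive overlap present
#' in the graph (falling back to `epsilon` when no edge has a common
#' neighbor); under `"fixed"` it is the constant `epsilon`.
#'
#' @param g An undirected simple graph with at least one edge.
#' @param floor_policy `"min_positive"` (default) or `"fixed"`.
#' @param epsilon Positive constant used by the `"fixed"` policy and as the
#'   all-zero fallback of `"min_positive"`. Default `1e-6`.
#' @param method Overlap formula passed to the per-edge computation; see
#'   [tie_overlap()].
#' @return A tibble of class `tie_tbl` with one row per edge: columns `from`,
#'   `to` (vertex ids, `from < to`), `n_common`, `overlap` (raw), `strength`
#'   (floored, in `(0, 1]`), `floored` (logical). Attributes `floor_value`,
#'   `n_nodes`, and `floor_policy` record the flooring.
#' @examples
#' g <- toy_two_hubs(3)
#' compute_ties(g)
#' @export
compute_ties <- function(g, floor_policy = c("min_positive", "fixed"),
                         epsilon = 1e-6, method = c("overlap", "jaccard")) {
  floor_policy <- rlang::arg_match(floor_policy)
  method <- rlang::arg_match(method)
  validate_graph(g)
  if (igraph::ecount(g) == 0L) abort("graph has no edges")
  if (!is.numeric(epsilon) || epsilon <= 0) abort("`epsilon` must be > 0")

  el <- igraph::as_edgelist(g, names = FALSE)
  from <- pmin(el[, 1], el[, 2])
  to <- pmax(el[, 1], el[, 2])
  a <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  common <- a %*% a                       # common-neighbor counts for all pairs
  n_common <- as.numeric(common[cbind(from, to)])
  k <- igraph::degree(g)
  overlap <- overlap_value(n_common, k[from], k[to], method)

  floor_value <- if (floor_policy == "fixed") epsilon else {
    pos <- overlap[overlap > 0]
    if (length(pos) == 0L) epsilon else min(pos)
  }
  strength <- ifelse(overlap == 0, floor_value, overlap)

  out <- tibble(
    from = as.integer(from), to = as.integer(to),
    n_common = as.integer(n_common),
    overlap = overlap, strength = strength, floored = overlap == 0
  ) |> arrange(.data$from, .data$to)
  attr(out, "floor_value") <- floor_value
  attr(out, "floor_policy") <- floor_policy
  attr(out, "n_nodes") <- igraph::vcount(g)
  class(out) <- c("tie_tbl", class(out))
  out
}

#' @export
print.tie_tbl <- function(x, ...) {
  cat(sprintf("# Tie strengths: %d edges on %d nodes (floor %s = %.3g, %d floored)\n",
              nrow(x), attr(x, "n_nodes"), attr(x, "floor_policy"),
              attr(x, "floor_value"), sum(x$floored)))
  NextMethod()
}

# Long (both directions) view of a tie table: one row per ordered pair.
ties_directed <- function(ties) {
  bind_rows(
    tibble(node = ties$from, neighbor = ties$to, strength = ties$strength),
    tibble(node = ties$to, neighbor = ties$from, strength = ties$strength)
  )
}

#' Histogram of tie strengths
#'
#' Counts of edge strengths in `n_bins` equal-width bins over `[0, 1]`.
#'
#' @param ties A `tie_tbl` from [compute_ties()].
#' @param n_bins Number of bins (>= 1). Default 20.
#' @return A tibble with columns `bin`, `lower`, `upper`, `count`,
#'   `fraction`; counts sum to the number of edges.
#' @export
strength_histogram <- function(ties, n_bins = 20) {
  if (n_bins < 1) abort("`n_bins` must be >= 1")
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(ties$strength, breaks, left.open = TRUE), 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  tibble(
    bin = seq_len(n_bins),
    lower = breaks[-length(breaks)],
    upper = breaks[-1],
    count = counts,
    fraction = counts / nrow(ties)
  )
}

#' Fraction of edges whose strength was floored
#'
#' The share of edges with no common neighbors, i.e. whose strength is the
#' floor value. Near 1 on locally tree-like graphs (preferential-attachment
#' networks), low on clustered ones — the relational-diversity contrast.
#'
#' @param ties A `tie_tbl`.
#' @return A number in `[0, 1]`.
#' @export
floored_fraction <- function(ties) mean(ties$floored)

#' Best friends of a node
#'
#' The neighbor(s) of maximal tie strength. Under `"argmax_set"` all
#' maximizers are returned; under `"strict"` the unique maximizer, or an
#' empty set when the maximum is tied.
#'
#' @param ties A `tie_tbl`.
#' @param i Vertex id with at least one neighbor.
#' @param tie_policy `"argmax_set"` (default) or `"strict"`.
#' @return Integer vector of vertex ids (possibly empty under `"strict"`).
#' @export
best_friends <- function(ties, i, tie_policy = c("argmax_set", "strict")) {
  tie_policy <- rlang::arg_match(tie_policy)
  d <- ties_directed(ties)
  d <- d[d$node == i, ]
  if (nrow(d) == 0L) abort(sprintf("node %s has no neighbors", i))
  best <- d$neighbor[d$strength == max(d$strength)]
  if (tie_policy == "strict" && length(best) > 1L) return(integer(0))
  sort(as.integer(best))
}

#' Mutual-best-friend pairs
#'
#' Edges `(i, j)` such that `j` is among `i`'s best friends and vice versa —
#' the reciprocal ties that act as cooperation allies under strong
#' investment preference.
#'
#' @param ties A `tie_tbl`.
#' @param tie_policy Tie-breaking policy, as in [best_friends()].
#' @return A tibble with columns `from`, `to`, `strength`, one row per
#'   unordered mutual pair.
#' @export
mutual_best_pairs <- function(ties, tie_policy = c("argmax_set", "strict")) {
  tie_policy <- rlang::arg_match(tie_policy)
  d <- ties_directed(ties) |>
    group_by(.data$node) |>
    mutate(
      is_best = .data$strength == max(.data$strength),
      n_best = sum(.data$strength == max(.data$strength))
    ) |>
    ungroup()
  if (tie_policy == "strict") d$is_best <- d$is_best & d$n_best == 1L
  b <- d[d$is_best, c("node", "neighbor", "strength")]
  key <- paste(b$node, b$neighbor)
  rev_key <- paste(b$neighbor, b$node)
  mut <- b[rev_key %in% key & b$node < b$neighbor, ]
  tibble(from = as.integer(mut$node), to = as.integer(mut$neighbor),
         strength = mut$strength)
}

#' Count mutual-best-friend pairs
#'
#' @inheritParams mutual_best_pairs
#' @return Number of unordered mutual-best-friend pairs.
#' @export
count_mutual_best_pairs <- function(ties, tie_policy = c("argmax_set", "strict")) {
  nrow(mutual_best_pairs(ties, tie_policy))
}

#' Write tie strengths as a three-column TSV
#'
#' @param ties A `tie_tbl`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ties <- function(ties, path) {
  utils::write.table(ties[, c("from", "to", "strength")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
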