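# One-round payoffs of the relation-weighted donation game.
#
# A cooperator x with degree k_x spends a total investment c * k_x per round,
# split across neighbors in proportion to tie strength raised to the
# preference exponent alpha. Each unit of investment received delivers a
# benefit b/c to the recipient, so a neighbor j of cooperator x receives
#     b * k_x * w_xj^alpha / sum_z w_xz^alpha.
# alpha = 0 recovers the classical donation game (every neighbor of a
# cooperator receives exactly b); alpha = Inf sends everything to the
# strongest tie(s). Defectors spend nothing.

#' Game parameters for the relation-weighted donation game
#'
#' @param b Benefit delivered per unit of classical investment; must exceed
#'   `c`. Default 1.
#' @param c Cost per neighbor borne by a cooperator (total spend `c * k`);
#'   must satisfy `0 < c < b`. Default 0.3.
#' @param alpha Preference exponent, `>= 0` or `Inf`. `0` splits investment
#'   equally (classical donation game); `Inf` gives everything to the
#'   best friend(s). Default 1.
#' @param K Selection noise (bounded rationality) of the Fermi imitation
#'   rule; must be positive. Default 0.1.
#' @return A list of class `game_params`.
#' @examples
#' game_params(b = 1, c = 0.5, alpha = Inf)
#' @export
game_params <- function(b = 1, c = 0.3, alpha = 1, K = 0.1) {
  if (!is.numeric(b) || !is.numeric(c) || c <= 0 || b <= c) {
    abort("need 0 < c < b")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0) {
    abort("`alpha` must be >= 0 (Inf allowed)")
  }
  if (!is.numeric(K) || K <= 0) abort("`K` must be > 0")
  structure(list(b = b, c = c, alpha = alpha, K = K), class = "game_params")
}

#' @export
print.game_params <- function(x, ...) {
  cat(sprintf("game_params: b = %g, c = %g, alpha = %s, K = %g\n",
              x$b, x$c, format(x$alpha), x$K))
  invisible(x)
}

# Normalized allocation weights for one node given its incident strengths.
# Strengths are scaled by their maximum before exponentiation so large
# finite alpha cannot underflow all weights to zero; alpha = Inf is computed
# exactly as a uniform split over the argmax set.
alloc_from_strengths <- function(w, alpha) {
  if (is.infinite(alpha)) {
    best <- w == max(w)
    return(best / sum(best))
  }
  u <- (w / max(w))^alpha
  u / sum(u)
}

#' Investment allocation weights of a cooperator
#'
#' The fraction of a cooperator's total investment that goes to each of its
#' neighbors: `w^alpha` of the tie strength, normalized over the node's
#' edges. `alpha = 0` gives the uniform split `1/k`; `alpha = Inf` splits
#' uniformly over the maximal-strength neighbor(s).
#'
#' @param ties A `tie_tbl` from [compute_ties()].
#' @param i Vertex id with degree >= 1.
#' @param alpha Preference exponent (`>= 0` or `Inf`).
#' @return A tibble with columns `neighbor`, `strength`, `weight`; weights
#'   sum to 1.
#' @export
allocation_weights <- function(ties, i, alpha) {
  d <- ties_directed(ties)
  d <- d[d$node == i, ]
  if (nrow(d) == 0L) abort(sprintf("node %s has no neighbors", i))
  d <- d[order(d$neighbor), ]
  tibble(
    neighbor = as.integer(d$neighbor),
    strength = d$strength,
    weight = alloc_from_strengths(d$strength, alpha)
  )
}

# n x n sparse delivery matrix D with D[x, y] = b * k_y * weight_y(x): the
# benefit x receives per round from y if y cooperates. One-round payoffs are
# then P = D %*% isC - c * k * isC, a single sparse matvec per generation.
delivery_matrix <- function(ties, params) {
  n <- attr(ties, "n_nodes")
  d <- ties_directed(ties) |>
    group_by(.data$node) |>
    mutate(weight = alloc_from_strengths(.data$strength, params$alpha)) |>
    ungroup()
  k <- tabulate(d$node, nbins = n)
  Matrix::sparseMatrix(
    i = d$neighbor, j = d$node,
    x = params$b * k[d$node] * d$weight,
    dims = c(n, n)
  )
}

#' One-round payoffs for every player
#'
#' Computes each player's payoff for a single round: the benefits received
#' from all cooperating neighbors (allocation-weighted as described in
#' [allocation_weights()]) minus, for cooperators, the total investment
#' `c * k`. In an all-defector population every payoff is zero.
#'
#' @param g An undirected simple graph.
#' @param ties Tie strengths of `g` from [compute_ties()].
#' @param strategies Per-node strategy: a character vector of `"C"`/`"D"` or
#'   a logical vector (`TRUE` = cooperate), length `vcount(g)`.
#' @param params A [game_params()] object.
#' @return A tibble with columns `node`, `strategy` (`"C"`/`"D"`), `degree`,
#'   `payoff`.
#' @examples
#' g <- toy_two_hubs(3)
#' ties <- compute_ties(g)
#' s <- c("C", "C", "D", "D", "D")  # hubs cooperate
#' round_payoffs(g, ties, s, game_params(b = 1, c = 0.5, alpha = Inf))
#' @export
round_payoffs <- function(g, ties, strategies, params) {
  n <- igraph::vcount(g)
  is_c <- as_strategy_logical(strategies, n)
  if (attr(ties, "n_nodes") != n) abort("`ties` and `g` disagree on node count")
  dm <- delivery_matrix(ties, params)
  k <- unname(igraph::degree(g))
  payoff <- as.numeric(dm %*% is_c) - params$c * k * is_c
  tibble(
    node = seq_len(n),
    strategy = ifelse(is_c, "C", "D"),
    degree = as.integer(k),
    payoff = payoff
  )
}

# Normalize a strategy representation to logical is-cooperator.
as_strategy_logical <- function(strategies, n) {
  if (is.logical(strategies)) {
    s <- strategies
  } else if (is.character(strategies)) {
    if (!all(strategies %in% c("C", "D"))) abort("strategies must be \"C\" or \"D\"")
    s <- strategies == "C"
  } else {
    abort("`strategies` must be logical or a \"C\"/\"D\" character vector")
  }
  if (length(s) != n || anyNA(s)) {
    abort(sprintf("`strategies` must have one non-missing entry per node (%d)", n))
  }
  s
}
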