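# Synchronous Fermi-rule imitation dynamics.
#
# Each generation: payoffs are computed for the current strategy profile;
# every player independently draws one neighbor uniformly at random and
# adopts that neighbor's strategy with the Fermi probability
#     1 / (1 + exp((P_x - P_y) / K));
# all updates are applied simultaneously from the same payoff snapshot.
# All-C and all-D profiles are absorbing.

#' Fermi imitation probability
#'
#' Probability that a player with payoff `p_x` adopts the strategy of a
#' model with payoff `p_y` under selection noise `K`:
#' `1 / (1 + exp((p_x - p_y) / K))`. Small `K` approaches deterministic
#' imitation of the better payoff; large `K` approaches a coin flip.
#'
#' @param p_x Payoff of the focal (imitating) player.
#' @param p_y Payoff of the model player.
#' @param K Selection noise, `> 0`.
#' @return Probability in `[0, 1]`; vectorized over payoffs.
#' @export
fermi_probability <- function(p_x, p_y, K) {
  if (!is.numeric(K) || any(K <= 0)) abort("`K` must be > 0")
  # clamp the exponent so extreme payoff gaps saturate instead of overflowing
  z <- pmin(pmax((p_x - p_y) / K, -745), 745)
  1 / (1 + exp(z))
}

# Flat adjacency (CSR-style) for O(1) vectorized neighbor sampling:
# neighbors of x are nbr[(ptr[x]+1):(ptr[x]+k[x])].
flat_adjacency <- function(g) {
  adj <- igraph::as_adj_list(g)
  k <- lengths(adj)
  list(nbr = as.integer(unlist(adj)), ptr = c(0L, cumsum(k))[seq_along(k)],
       k = as.integer(k))
}

# One synchronous generation given precomputed structures. Consumes two
# runif(n) vectors in node-id order: neighbor choice, then imitation flip.
step_strategies <- function(is_c, dm, k, c_cost, K, fa) {
  n <- length(is_c)
  payoff <- as.numeric(dm %*% is_c) - c_cost * k * is_c
  pick <- fa$ptr + floor(runif(n) * fa$k) + 1L
  y <- fa$nbr[pick]
  p_adopt <- fermi_probability(payoff, payoff[y], K)
  flip <- runif(n) < p_adopt
  out <- is_c
  out[flip] <- is_c[y][flip]
  out
}

#' One synchronous update generation
#'
#' Computes one-round payoffs for the current profile and applies the Fermi
#' imitation rule to every player simultaneously (one uniformly drawn
#' neighbor each). Exposed mainly for testing and for stepping a process by
#' hand; [run_evolution()] is the standard driver.
#'
#' @inheritParams round_payoffs
#' @return The next strategy profile, as a `"C"`/`"D"` character vector.
#' @export
generation_step <- function(g, ties, strategies, params) {
  n <- igraph::vcount(g)
  is_c <- as_strategy_logical(strategies, n)
  dm <- delivery_matrix(ties, params)
  fa <- flat_adjacency(g)
  out <- step_strategies(is_c, dm, unname(igraph::degree(g)), params$c, params$K, fa)
  ifelse(out, "C", "D")
}

#' Run the evolutionary process
#'
#' Iterates synchronous Fermi-rule generations for `transient + window`
#' steps and estimates the equilibrium cooperator fraction as the mean over
#' the final `window` generations. Runs that absorb at all-C or all-D exit
#' early; the recorded trace is padded with the constant tail so window
#' averaging is unchanged.
#'
#' @param g An undirected simple graph.
#' @param ties Tie strengths of `g` from [compute_ties()].
#' @param params A [game_params()] object.
#' @param init Initial strategy profile (see [init_random_half()],
#'   [init_seeded_pairs()]), as `"C"`/`"D"` or logical.
#' @param transient Number of burn-in generations (default 2000).
#' @param window Number of generations averaged for the equilibrium estimate
#'   (default 500).
#' @param seed Integer seed; the whole trace is reproducible from it.
#' @return An object of class `evolution_trace`: a list with `trace` (tibble
#'   of `generation`, `f_c`), `equilibrium_f_c`, `absorbed_at` (generation of
#'   absorption or `NA`), `params`, `seed`, `n_nodes`. Has [tidy()],
#'   [glance()] and [autoplot()] methods.
#' @examples
#' g <- toy_two_hubs(3)
#' ties <- compute_ties(g)
#' tr <- run_evolution(g, ties, game_params(c = 0.5, alpha = Inf),
#'                     init_seeded_pairs(g, ties, 1, seed = 1),
#'                     transient = 50, window = 10, seed = 1)
#' glance(tr)
#' @export
run_evolution <- function(g, ties, params, init, transient = 2000,
                          window = 500, seed = 1L) {
  if (transient < 0 || window < 1) abort("need transient >= 0 and window >= 1")
  n <- igraph::vcount(g)
  is_c <- as_strategy_logical(init, n)
  dm <- delivery_matrix(ties, params)
  fa <- flat_adjacency(g)
  k <- unname(igraph::degree(g))
  total <- transient + window

  f_c <- numeric(total + 1)
  f_c[1] <- mean(is_c)
  absorbed_at <- NA_integer_
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  gen <- 0L
  if (f_c[1] %in% c(0, 1)) absorbed_at <- 0L
  while (gen < total && is.na(absorbed_at)) {
    is_c <- step_strategies(is_c, dm, k, params$c, params$K, fa)
    gen <- gen + 1L
    f_c[gen + 1] <- mean(is_c)
    if (f_c[gen + 1] %in% c(0, 1)) absorbed_at <- gen
  }
  if (!is.na(absorbed_at) && gen < total) {
    f_c[(gen + 2):(total + 1)] <- f_c[gen + 1]   # pad constant absorbed tail
  }

  structure(list(
    trace = tibble(generation = 0:total, f_c = f_c),
    equilibrium_f_c = mean(f_c[(transient + 2):(total + 1)]),
    absorbed_at = absorbed_at,
    params = params,
    seed = as.integer(seed),
    n_nodes = n,
    transient = as.integer(transient),
    window = as.integer(window)
  ), class = "evolution_trace")
}

#' @export
print.evolution_trace <- function(x, ...) {
  cat(sprintf(
    "evolution_trace: %d nodes, %d+%d generations, seed %d\n  equilibrium f_c = %.4f%s\n",
    x$n_nodes, x$transient, x$window, x$seed, x$equilibrium_f_c,
    if (!is.na(x$absorbed_at)) sprintf(" (absorbed at generation %d)", x$absorbed_at) else ""
  ))
  invisible(x)
}

#' Tidy an evolution trace into a per-generation tibble
#'
#' @param x An `evolution_trace`.
#' @param ... Unused.
#' @return A tibble with columns `generation`, `f_c`, `seed`, `alpha`, `c`.
#' @exportS3Method generics::tidy
tidy.evolution_trace <- function(x, ...) {
  x$trace |>
    mutate(seed = x$seed, alpha = x$params$alpha, c = x$params$c)
}

#' One-row summary of an evolution run
#'
#' @param x An `evolution_trace`.
#' @param ... Unused.
#' @return A one-row tibble: `n_nodes`, `b`, `c`, `alpha`, `K`, `seed`,
#'   `transient`, `window`, `equilibrium_f_c`, `absorbed_at`.
#' @exportS3Method generics::glance
glance.evolution_trace <- function(x, ...) {
  tibble(
    n_nodes = x$n_nodes, b = x$params$b, c = x$params$c,
    alpha = x$params$alpha, K = x$params$K, seed = x$seed,
    transient = x$transient, window = x$window,
    equilibrium_f_c = x$equilibrium_f_c, absorbed_at = x$absorbed_at
  )
}

#' Plot the cooperator-fraction time series of a run
#'
#' @param object An `evolution_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.evolution_trace <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$generation, y = .data$f_c)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = "generation", y = expression(f[c]),
      title = sprintf("alpha = %s, c = %g, equilibrium f_c = %.3f",
                      format(object$params$alpha), object$params$c,
                      object$equilibrium_f_c)
    ) +
    ggplot2::theme_minimal()
}

#' Write a trace as TSV plus a JSON metadata sidecar
#'
#' @param x An `evolution_trace`.
#' @param path Output TSV path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(x, path) {
  utils::write.table(x$trace, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(
    params = unclass(x$params), seed = x$seed, n_nodes = x$n_nodes,
    transient = x$transient, window = x$window,
    equilibrium_f_c = x$equilibrium_f_c,
    absorbed_at = if (is.na(x$absorbed_at)) NULL else x$absorbed_at
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Random half-and-half initial condition
#'
#' Exactly `floor(N / 2)` cooperators placed uniformly at random.
#'
#' @param g An undirected simple graph.
#' @param seed Integer seed for the placement.
#' @return A `"C"`/`"D"` character vector of length `vcount(g)`.
#' @export
init_random_half <- function(g, seed = 1L) {
  n <- igraph::vcount(g)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  s <- rep("D", n)
  s[sample.int(n, n %/% 2)] <- "C"
  s
}

#' Seed cooperation on mutual-best-friend pairs
#'
#' Selects `n_pairs` mutual-best-friend pairs uniformly at random and marks
#' their members as cooperators; everyone else defects. The invasion
#' experiment: can a handful of reciprocal allies take over the population?
#'
#' @param g An undirected simple graph.
#' @param ties Tie strengths of `g`.
#' @param n_pairs Number of pairs to seed (0 gives all-D).
#' @param seed Integer seed for the pair selection.
#' @param tie_policy Best-friend tie policy, see [best_friends()].
#' @return A `"C"`/`"D"` character vector of length `vcount(g)`.
#' @export
init_seeded_pairs <- function(g, ties, n_pairs, seed = 1L,
                              tie_policy = c("argmax_set", "strict")) {
  n <- igraph::vcount(g)
  s <- rep("D", n)
  if (n_pairs == 0) return(s)
  pairs <- mutual_best_pairs(ties, tie_policy)
  if (nrow(pairs) < n_pairs) {
    abort(sprintf("requested %d mutual-best-friend pairs but only %d exist",
                  n_pairs, nrow(pairs)))
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  chosen <- pairs[sample.int(nrow(pairs), n_pairs), ]
  s[c(chosen$from, chosen$to)] <- "C"
  s
}
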