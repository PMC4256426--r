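# Shared fixtures and independent oracles.

# Random connected-ish simple graph via G(n, p); guaranteed >= 1 edge.
random_test_graph <- function(n, p = 0.3, seed = 1) {
  withr::local_seed(seed)
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::ecount(g) >= 1) break
  }
  igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  g
}

# Brute-force overlap by explicit set intersection, no matrix algebra.
oracle_overlap <- function(g, i, j) {
  ni <- as.integer(igraph::neighbors(g, i))
  nj <- as.integer(igraph::neighbors(g, j))
  n_common <- length(intersect(ni, nj))
  if (n_common == 0) return(0)
  n_common / ((length(ni) - 1) + (length(nj) - 1) - n_common)
}

# Independent per-node allocation: plain loops over a node's incident edges.
oracle_alloc <- function(strengths, alpha) {
  if (is.infinite(alpha)) {
    best <- abs(strengths - max(strengths)) < 1e-15
    return(best / sum(best))
  }
  raw <- numeric(length(strengths))
  for (z in seq_along(strengths)) raw[z] <- (strengths[z] / max(strengths))^alpha
  raw / sum(raw)
}

# Brute-force payoffs: enumerate every (cooperator, neighbor) transfer with
# nested loops, looking strengths up edge by edge.
oracle_payoffs <- function(g, ties, strategies, params) {
  n <- igraph::vcount(g)
  is_c <- strategies == "C"
  k <- igraph::degree(g)
  strength_of <- function(a, b) {
    row <- ties[(ties$from == min(a, b)) & (ties$to == max(a, b)), ]
    row$strength
  }
  payoff <- numeric(n)
  for (y in seq_len(n)) {
    if (!is_c[y]) next
    payoff[y] <- payoff[y] - params$c * k[y]
    nbrs <- sort(as.integer(igraph::neighbors(g, y)))
    if (length(nbrs) == 0) next     # isolated cooperator: nothing to dispense
    w <- vapply(nbrs, function(x) strength_of(y, x), numeric(1))
    share <- oracle_alloc(w, params$alpha)
    for (z in seq_along(nbrs)) {
      payoff[nbrs[z]] <- payoff[nbrs[z]] + params$b * k[y] * share[z]
    }
  }
  payoff
}

random_strategies <- function(n, seed) {
  withr::local_seed(seed)
  sample(c("C", "D"), n, replace = TRUE)
}
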