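# Synthetic networks with controllable relational diversity.
#
# Three families: preferential attachment (near-zero neighborhood overlap on
# most edges — the negative control), a relaxed-caveman clustered family
# (dense communities, high overlap — the stand-in for real social networks),
# and the exact two-hub toy used for closed-form payoff checks.

#' Preferential-attachment (Barabasi-Albert) graph
#'
#' The standard growing-network construction: starting from `m` unconnected
#' seed vertices, each new vertex attaches to `m` distinct existing vertices
#' chosen with probability proportional to degree (uniformly for the first
#' arrival), giving exactly `m * (n - m)` edges and a heavy-tailed degree
#' distribution.
#'
#' @param n Number of vertices.
#' @param m Edges added per new vertex, `1 <= m < n`.
#' @param seed Integer seed; the construction is fully deterministic given it.
#' @return An undirected simple [igraph][igraph::graph] object with `n`
#'   vertices and `m * (n - m)` edges.
#' @export
barabasi_albert <- function(n, m, seed = 1L) {
  if (m < 1 || m >= n) abort("need 1 <= m < n")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  # repeated-nodes sampling: each endpoint appearance is one lottery ticket,
  # so uniform draws from the ticket list are degree-proportional draws
  from <- integer(m * (n - m)); to <- integer(m * (n - m))
  tickets <- integer(0)
  targets <- seq_len(m)                 # first arrival wires to all seeds
  e <- 0L
  for (v in (m + 1L):n) {
    idx <- e + seq_len(m)
    from[idx] <- v; to[idx] <- targets
    e <- e + m
    tickets <- c(tickets, targets, rep.int(v, m))
    # sample m distinct targets, degree-proportionally, for the next arrival
    targets <- integer(0)
    while (length(targets) < m) {
      cand <- tickets[sample.int(length(tickets), m - length(targets), replace = TRUE)]
      targets <- unique(c(targets, cand))
    }
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  igraph::V(g)$name <- as.character(seq_len(n))
  validate_graph(g)
  g
}

#' Preferential-attachment graph matched to a target edge count
#'
#' Chooses the integer `m` whose `m * (n - m)` edge count is closest to
#' `target_edges`, then calls [barabasi_albert()]. Used to build the
#' same-size negative control for a clustered or empirical network.
#'
#' @param n Number of vertices.
#' @param target_edges Desired edge count.
#' @param seed Integer seed.
#' @return An undirected simple graph.
#' @export
barabasi_albert_matched <- function(n, target_edges, seed = 1L) {
  ms <- seq_len(min(n - 1L, max(2L, ceiling(2 * target_edges / n))))
  m <- ms[which.min(abs(ms * (n - ms) - target_edges))]
  barabasi_albert(n, m, seed)
}

#' Clustered (relaxed-caveman) graph
#'
#' Partitions `n` vertices into cliques of `community_size` and then rewires
#' each edge with probability `rewire_p` to a uniformly random vertex
#' (avoiding loops and duplicates). Low `rewire_p` keeps dense overlapping
#' neighborhoods — strong, diverse ties; raising it erodes the overlap. The
#' largest connected component is returned.
#'
#' @param n Number of vertices before taking the largest component.
#' @param community_size Clique size, `>= 4`.
#' @param rewire_p Per-edge rewiring probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return An undirected simple graph (largest component; vertex count can
#'   be below `n` when `rewire_p > 0` disconnects stragglers).
#' @export
clustered_graph <- function(n, community_size, rewire_p = 0.1, seed = 1L) {
  if (community_size < 4) abort("`community_size` must be >= 4")
  if (rewire_p < 0 || rewire_p > 1) abort("`rewire_p` must be in [0, 1]")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  n_comm <- max(1L, n %/% community_size)
  member <- rep(seq_len(n_comm), length.out = n)
  pairs <- do.call(rbind, lapply(seq_len(n_comm), function(cm) {
    v <- which(member == cm)
    if (length(v) < 2) return(NULL)
    t(utils::combn(v, 2))
  }))
  # relaxed-caveman rewiring: move one endpoint to a random vertex
  edge_env <- new.env(hash = TRUE, size = nrow(pairs) * 2L)
  for (r in seq_len(nrow(pairs))) {
    assign(paste(pairs[r, 1], pairs[r, 2]), TRUE, envir = edge_env)
  }
  rewire <- runif(nrow(pairs)) < rewire_p
  for (r in which(rewire)) {
    u <- pairs[r, 1]; v_old <- pairs[r, 2]
    for (attempt in 1:50) {
      w <- sample.int(n, 1L)
      if (w == u) next
      key <- paste(min(u, w), max(u, w))
      if (!exists(key, envir = edge_env, inherits = FALSE)) {
        rm(list = paste(min(u, v_old), max(u, v_old)), envir = edge_env)
        assign(key, TRUE, envir = edge_env)
        pairs[r, 2] <- w
        break
      }
    }
  }
  pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  g <- igraph::simplify(g)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  comp <- igraph::components(g)
  g <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
  igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  validate_graph(g)
  g
}

#' Two-hub toy graph
#'
#' Two hubs joined to each other, each also joined to the same `n_leaves`
#' leaves. Every neighbor of one hub other than the partner is shared, so
#' the hub-hub tie strength is exactly 1 while every hub-leaf tie has
#' strength `1 / n_leaves`: the minimal fixture where a mutual-best-friend
#' cooperator pair either collapses (equal-split investment) or takes over
#' (best-friend investment).
#'
#' @param n_leaves Number of shared leaves, `>= 1` (`1` gives a triangle).
#' @return An undirected simple graph with vertices `1` and `2` as the hubs
#'   (recorded in the `hubs` graph attribute) and `n_leaves` leaves.
#' @export
toy_two_hubs <- function(n_leaves = 3) {
  if (n_leaves < 1) abort("`n_leaves` must be >= 1")
  leaves <- 2L + seq_len(n_leaves)
  el <- rbind(c(1L, 2L), cbind(1L, leaves), cbind(2L, leaves))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::V(g)$name <- as.character(seq_len(2L + n_leaves))
  g <- igraph::set_graph_attr(g, "hubs", c(1L, 2L))
  validate_graph(g)
  g
}

#' Clustered graph with hub-pair communities
#'
#' A clustered family with within-neighborhood strength diversity: each
#' community of `community_size` vertices has two hubs adjacent to each
#' other and to every member, while the remaining leaves are wired in a
#' ring plus `q` additional random intra-community leaf-leaf links each;
#' edges are then rewired with probability `rewire_p` as in
#' [clustered_graph()] and the largest component is returned.
#'
#' Unlike clique communities — where every within-community tie has the
#' same strength and investment preference has nothing to act on — the
#' hub/leaf degree contrast makes the hub-hub edge the unique strongest tie
#' of both hubs, producing reciprocal unique best friendships whose joint
#' payoff under strong preference exceeds anything a defector can harvest
#' from the low-degree leaves. This is the regime in which concentrating
#' investment on strong ties rescues cooperation.
#'
#' @param n Number of vertices before taking the largest component.
#' @param community_size Community size, `>= 6` (2 hubs + at least 4 leaves).
#' @param q Extra random leaf-leaf links per leaf within its community
#'   beyond the ring (default 0; must leave leaves sparser than hubs).
#' @param rewire_p Per-edge rewiring probability in `[0, 1]` (default 0.1).
#' @param seed Integer seed.
#' @return An undirected simple graph.
#' @export
community_hubs_graph <- function(n, community_size, q = 0, rewire_p = 0.1,
                                 seed = 1L) {
  if (community_size < 6) abort("`community_size` must be >= 6")
  if (q < 0 || q > community_size - 3) abort("`q` must be in [0, community_size - 3]")
  if (rewire_p < 0 || rewire_p > 1) abort("`rewire_p` must be in [0, 1]")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  n_comm <- max(1L, n %/% community_size)
  n_used <- n_comm * community_size
  from <- integer(0); to <- integer(0)
  for (cm in seq_len(n_comm)) {
    v <- ((cm - 1L) * community_size + 1L):(cm * community_size)
    h1 <- v[1]; h2 <- v[2]; leaves <- v[-(1:2)]
    from <- c(from, h1, rep(h1, length(leaves)), rep(h2, length(leaves)))
    to <- c(to, h2, leaves, leaves)
    from <- c(from, leaves)                       # leaf ring
    to <- c(to, c(leaves[-1], leaves[1]))
    if (q > 0) {
      for (l in leaves) {
        tg <- sample(setdiff(leaves, l), q)
        from <- c(from, rep(l, q)); to <- c(to, tg)
      }
    }
  }
  m <- cbind(pmin(from, to), pmax(from, to))
  m <- m[!duplicated(paste(m[, 1], m[, 2])), , drop = FALSE]
  rw <- which(runif(nrow(m)) < rewire_p)
  for (r in rw) {
    w <- sample.int(n_used, 1L)
    if (w != m[r, 1]) m[r, 2] <- w
  }
  g <- igraph::simplify(igraph::graph_from_edgelist(m, directed = FALSE))
  comp <- igraph::components(g)
  g <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
  igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  validate_graph(g)
  g
}

#' Erdos-Renyi G(n, p) graph (largest component)
#'
#' Thin wrapper around [igraph::sample_gnp()] retaining the largest
#' connected component, for use as an additional unclustered control.
#'
#' @param n Number of vertices.
#' @param p Edge probability.
#' @param seed Integer seed.
#' @return An undirected simple graph.
#' @export
erdos_renyi <- function(n, p, seed = 1L) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  comp <- igraph::components(g)
  g <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
  igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  validate_graph(g)
  g
}

#' Build a graph from a generator specification
#'
#' Dispatches on a list with a `family` field — one of `"ba"`,
#' `"clustered"`, `"community_hubs"`, `"toy"`, `"erdos_renyi"` — plus that
#' family's parameters
#' (see the individual generators). This is the form experiment configs use
#' to describe a network source.
#'
#' @param spec A named list, e.g.
#'   `list(family = "clustered", n = 500, community_size = 20, rewire_p = 0.1)`.
#' @param seed Integer seed used when the spec does not carry its own.
#' @return An undirected simple graph.
#' @export
graph_from_spec <- function(spec, seed = 1L) {
  if (is.null(spec$family)) abort("generator spec needs a `family` field")
  seed <- spec$seed %||% seed
  switch(spec$family,
    ba = if (!is.null(spec$target_edges)) {
      barabasi_albert_matched(spec$n, spec$target_edges, seed)
    } else {
      barabasi_albert(spec$n, spec$m, seed)
    },
    clustered = clustered_graph(spec$n, spec$community_size,
                                spec$rewire_p %||% 0.1, seed),
    community_hubs = community_hubs_graph(spec$n, spec$community_size,
                                          spec$q %||% 4,
                                          spec$rewire_p %||% 0.1, seed),
    toy = toy_two_hubs(spec$n_leaves %||% 3),
    erdos_renyi = erdos_renyi(spec$n, spec$p, seed),
    abort(sprintf("unknown generator family: %s", spec$family))
  )
}
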