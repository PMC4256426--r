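# Reproducible experiment runner: parameter sweeps, time series, seeded
# invasions, and network diagnostics, all driven by a serializable config.
#
# A config is a plain named list (YAML/JSON on disk) with:
#   network:  file path (edge list) or generator spec (see graph_from_spec)
#   game:     b, K, alpha (vector, "inf" allowed), c (vector)
#   protocol: transient, window, replicates, base_seed
#   init:     "random_half" or list(seeded_pairs = n)
# Replicate r uses seed base_seed + r - 1, so every row of a result table
# can be reproduced in isolation.

default_config <- function() {
  list(
    network = list(family = "clustered", n = 500, community_size = 20,
                   rewire_p = 0.1),
    game = list(b = 1, c = 0.3, alpha = 1, K = 0.1),
    protocol = list(transient = 2000, window = 500, replicates = 10,
                    base_seed = 1),
    init = "random_half"
  )
}

#' Read an experiment configuration
#'
#' Loads a YAML or JSON config and fills unspecified fields from the
#' defaults (clustered network of 500 nodes; `b = 1`, `c = 0.3`, `K = 0.1`;
#' transient 2000, window 500, 10 replicates; random half-and-half start).
#' The string `"inf"` (any case) in the alpha grid denotes the best-friend
#' limit.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A config list with a `hash` attribute identifying its content.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config not found: ", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  as_config(cfg)
}

#' Normalize and validate a configuration list
#'
#' @param cfg A named list with any of `network`, `game`, `protocol`,
#'   `init`; missing fields take the defaults.
#' @return The completed config with a content `hash` attribute.
#' @export
as_config <- function(cfg) {
  base <- default_config()
  for (sec in c("network", "game", "protocol")) {
    if (!is.null(cfg[[sec]])) {
      if (is.character(cfg[[sec]])) base[[sec]] <- cfg[[sec]]
      else base[[sec]] <- modifyList(base[[sec]], as.list(cfg[[sec]]))
    }
  }
  if (!is.null(cfg$init)) base$init <- cfg$init
  base$game$alpha <- parse_alpha(base$game$alpha)
  if (length(base$game$alpha) == 0 || length(base$game$c) == 0) {
    abort("alpha and c grids must be nonempty")
  }
  if (base$protocol$replicates < 1) abort("`replicates` must be >= 1")
  # canonicalize numeric types so a config hashes identically before and
  # after a YAML/JSON round trip (parsers return integers where possible)
  base <- rapply(base, function(v) if (is.integer(v)) as.double(v) else v,
                 how = "replace")
  attr(base, "hash") <- config_hash(base)
  base
}

parse_alpha <- function(a) {
  unname(vapply(a, function(x) {
    if (is.character(x) && tolower(x) %in% c("inf", "infinite")) Inf
    else as.numeric(x)
  }, numeric(1)))
}

config_hash <- function(cfg) {
  attr(cfg, "hash") <- NULL
  rlang::hash(cfg)
}

#' Write a configuration to YAML or JSON
#'
#' Inverse of [read_config()]: `read_config(write_config(cfg, path))`
#' yields an identical config. Infinite alphas are serialized as `"inf"`.
#'
#' @param cfg A config list.
#' @param path Destination (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  out <- cfg
  attr(out, "hash") <- NULL
  out$game$alpha <- ifelse(is.infinite(out$game$alpha), "inf",
                           as.character(out$game$alpha))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}

# Resolve the config's network section into a graph.
config_graph <- function(cfg, seed) {
  nw <- cfg$network
  if (is.character(nw)) return(read_edge_list(nw))
  if (!is.null(nw$path)) return(read_edge_list(nw$path))
  graph_from_spec(nw, seed = seed)
}

config_init <- function(cfg, g, ties, seed) {
  init <- cfg$init
  if (identical(init, "random_half")) return(init_random_half(g, seed = seed))
  if (is.list(init) && !is.null(init$seeded_pairs)) {
    return(init_seeded_pairs(g, ties, init$seeded_pairs, seed = seed))
  }
  abort("unknown init: use \"random_half\" or list(seeded_pairs = n)")
}

#' Run an (alpha, c) equilibrium sweep
#'
#' For every combination of the config's alpha and cost grids, runs
#' `replicates` independent evolutionary processes (replicate `r` seeded
#' with `base_seed + r - 1`) and records the equilibrium cooperator
#' fraction of each.
#'
#' @param cfg A config list (see [as_config()]) or a path readable by
#'   [read_config()].
#' @return A tibble of class `sweep_result`, one row per
#'   `(alpha, c, replicate)`: columns `alpha`, `c`, `replicate`, `seed`,
#'   `equilibrium_f_c`, `absorbed_at`; the config hash, base seed and graph
#'   size are carried as attributes. Use [summarise_sweep()] for per-cell
#'   medians and [autoplot()] for the equilibrium curves.
#' @export
run_sweep <- function(cfg) {
  cfg <- ensure_config(cfg)
  p <- cfg$protocol
  g <- config_graph(cfg, seed = p$base_seed)
  ties <- compute_ties(g)
  grid <- tidyr::expand_grid(
    alpha = cfg$game$alpha, c = cfg$game$c,
    replicate = seq_len(p$replicates)
  )
  res <- purrr::pmap(grid, function(alpha, c, replicate) {
    seed <- p$base_seed + replicate - 1
    gp <- game_params(b = cfg$game$b, c = c, alpha = alpha, K = cfg$game$K)
    init <- config_init(cfg, g, ties, seed = seed)
    tr <- run_evolution(g, ties, gp, init, transient = p$transient,
                        window = p$window, seed = seed)
    tibble(seed = seed, equilibrium_f_c = tr$equilibrium_f_c,
           absorbed_at = tr$absorbed_at)
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
  attr(out, "hash") <- attr(cfg, "hash")
  attr(out, "base_seed") <- p$base_seed
  attr(out, "n_nodes") <- igraph::vcount(g)
  class(out) <- c("sweep_result", class(out))
  out
}

#' Median equilibrium per sweep cell
#'
#' @param sweep A `sweep_result` from [run_sweep()].
#' @return A tibble with one row per `(alpha, c)`: `median_f_c`, `mean_f_c`,
#'   `n_replicates`.
#' @export
summarise_sweep <- function(sweep) {
  sweep |>
    as_tibble() |>
    group_by(.data$alpha, .data$c) |>
    summarise(
      median_f_c = median(.data$equilibrium_f_c),
      mean_f_c = mean(.data$equilibrium_f_c),
      n_replicates = n(),
      .groups = "drop"
    )
}

#' Plot sweep results as equilibrium-vs-cost curves
#'
#' @param object A `sweep_result`.
#' @param ... Unused.
#' @return A ggplot object: median equilibrium cooperator fraction against
#'   cost, one curve per alpha.
#' @exportS3Method ggplot2::autoplot
autoplot.sweep_result <- function(object, ...) {
  summarise_sweep(object) |>
    mutate(alpha = factor(format(.data$alpha))) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$c, y = .data$median_f_c,
                                 colour = .data$alpha, group = .data$alpha)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "cost c", y = expression("equilibrium " * f[c]),
                  colour = expression(alpha)) +
    ggplot2::theme_minimal()
}

#' Run time-series experiments
#'
#' One full evolutionary trace per (alpha, replicate) at the first cost of
#' the grid, optionally written to disk as TSV + JSON metadata.
#'
#' @param cfg A config list or path.
#' @param out_dir Optional directory; when given, each trace is written to
#'   `trace_alpha<alpha>_rep<r>.tsv` inside it.
#' @return A tibble with columns `alpha`, `replicate`, `seed`, and a
#'   list-column `trace` of `evolution_trace` objects.
#' @export
run_timeseries <- function(cfg, out_dir = NULL) {
  cfg <- ensure_config(cfg)
  p <- cfg$protocol
  g <- config_graph(cfg, seed = p$base_seed)
  ties <- compute_ties(g)
  cost <- cfg$game$c[1]
  grid <- tidyr::expand_grid(alpha = cfg$game$alpha,
                             replicate = seq_len(p$replicates))
  traces <- purrr::pmap(grid, function(alpha, replicate) {
    seed <- p$base_seed + replicate - 1
    gp <- game_params(b = cfg$game$b, c = cost, alpha = alpha, K = cfg$game$K)
    init <- config_init(cfg, g, ties, seed = seed)
    run_evolution(g, ties, gp, init, transient = p$transient,
                  window = p$window, seed = seed)
  })
  out <- grid |>
    mutate(seed = p$base_seed + .data$replicate - 1, trace = traces)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    purrr::pwalk(out, function(alpha, replicate, seed, trace) {
      write_trace(trace, file.path(out_dir, sprintf(
        "trace_alpha%s_rep%d.tsv", format(alpha), replicate)))
    })
  }
  out
}

#' Run a seeded-invasion experiment
#'
#' Starts from `n_pairs` mutual-best-friend pairs as the only cooperators
#' and reports, per replicate, whether cooperation took over the whole
#' population and at which generation.
#'
#' @param cfg A config list or path; its `init` is overridden by `n_pairs`.
#' @param n_pairs Number of mutual-best-friend pairs to seed.
#' @return A tibble, one row per replicate: `replicate`, `seed`,
#'   `equilibrium_f_c`, `reached_fixation` (logical), `fixation_generation`
#'   (`NA` when not reached). Attribute `n_mutual_pairs` records how many
#'   pairs the network offers.
#' @export
run_seeded <- function(cfg, n_pairs = 2) {
  cfg <- ensure_config(cfg)
  p <- cfg$protocol
  g <- config_graph(cfg, seed = p$base_seed)
  ties <- compute_ties(g)
  pairs <- mutual_best_pairs(ties)
  if (nrow(pairs) < n_pairs) {
    abort(sprintf("network has only %d mutual-best-friend pairs, %d requested",
                  nrow(pairs), n_pairs))
  }
  alpha <- cfg$game$alpha[1]
  cost <- cfg$game$c[1]
  gp <- game_params(b = cfg$game$b, c = cost, alpha = alpha, K = cfg$game$K)
  out <- purrr::map(seq_len(p$replicates), function(r) {
    seed <- p$base_seed + r - 1
    init <- init_seeded_pairs(g, ties, n_pairs, seed = seed)
    tr <- run_evolution(g, ties, gp, init, transient = p$transient,
                        window = p$window, seed = seed)
    fixed <- !is.na(tr$absorbed_at) && tr$equilibrium_f_c == 1
    tibble(replicate = r, seed = seed,
           equilibrium_f_c = tr$equilibrium_f_c,
           reached_fixation = fixed,
           fixation_generation = if (fixed) tr$absorbed_at else NA_integer_)
  }) |> bind_rows()
  attr(out, "n_mutual_pairs") <- nrow(pairs)
  out
}

#' Network diagnostics report
#'
#' Summarizes a network the way the relational-diversity analysis looks at
#' it: descriptive statistics, the tie-strength histogram, the fraction of
#' floored (no-common-neighbor) edges, and the mutual-best-friend pair
#' count under both tie policies.
#'
#' @param g An undirected simple graph, or anything [graph_from_spec()] or
#'   [read_edge_list()] accepts via a config's network section.
#' @param n_bins Bins for the strength histogram (default 20).
#' @return A list of class `network_report`: `stats` (one-row tibble),
#'   `histogram` (tibble), `floored_fraction`, `mutual_pairs_argmax`,
#'   `mutual_pairs_strict`, `floor_value`.
#' @export
describe_network <- function(g, n_bins = 20) {
  if (!igraph::is_igraph(g)) {
    g <- if (is.character(g)) read_edge_list(g) else graph_from_spec(g)
  }
  ties <- compute_ties(g)
  structure(list(
    stats = graph_stats(g),
    histogram = strength_histogram(ties, n_bins),
    floored_fraction = floored_fraction(ties),
    mutual_pairs_argmax = count_mutual_best_pairs(ties, "argmax_set"),
    mutual_pairs_strict = count_mutual_best_pairs(ties, "strict"),
    floor_value = attr(ties, "floor_value")
  ), class = "network_report")
}

#' @export
print.network_report <- function(x, ...) {
  cat("Network diagnostics\n-------------------\n")
  s <- x$stats
  cat(sprintf("  nodes %d, edges %d, mean degree %.2f, density %.4f\n",
              s$n_nodes, s$n_edges, s$mean_degree, s$density))
  cat(sprintf("  diameter %d, mean path length %.4f, clustering %.4f\n",
              s$diameter, s$mean_path_length, s$clustering))
  cat(sprintf("  floored edges: %.1f%% (floor value %.3g)\n",
              100 * x$floored_fraction, x$floor_value))
  cat(sprintf("  mutual best-friend pairs: %d (argmax set), %d (strict)\n",
              x$mutual_pairs_argmax, x$mutual_pairs_strict))
  invisible(x)
}

ensure_config <- function(cfg) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  else if (is.null(attr(cfg, "hash"))) cfg <- as_config(cfg)
  cfg
}

#' Write a sweep result table with provenance header
#'
#' TSV with `# config_hash` and `# base_seed` comment lines, so equal
#' hashes imply byte-identical tables.
#'
#' @param sweep A `sweep_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# config_hash: ", attr(sweep, "hash") %||% "NA"),
    paste0("# base_seed: ", attr(sweep, "base_seed") %||% "NA")
  ), con)
  utils::write.table(as_tibble(sweep), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
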