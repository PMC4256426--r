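# Plotting helpers beyond the autoplot methods.

#' Plot a tie-strength histogram
#'
#' Bar chart of the strength distribution of one or several networks; the
#' visual contrast between a clustered network (mass spread across
#' strengths) and a preferential-attachment one (almost all mass at the
#' floor) is the relational-diversity signature.
#'
#' @param ... Named `tie_tbl` objects, e.g.
#'   `plot_strength_distribution(facebook = t1, ba = t2)`.
#' @param n_bins Number of bins over `[0, 1]` (default 20).
#' @return A ggplot object.
#' @export
plot_strength_distribution <- function(..., n_bins = 20) {
  tl <- rlang::list2(...)
  if (is.null(names(tl)) || any(names(tl) == "")) {
    names(tl) <- paste0("network_", seq_along(tl))
  }
  df <- purrr::imap(tl, \(t, nm) {
    strength_histogram(t, n_bins) |> mutate(network = nm)
  }) |> bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$lower + .data$upper) / 2,
                                   y = .data$fraction, fill = .data$network)) +
    ggplot2::geom_col(position = "dodge", width = 1 / n_bins * 0.9) +
    ggplot2::labs(x = "tie strength w", y = "fraction of edges",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a degree distribution
#'
#' @param g An undirected simple graph.
#' @param log_log Use log-log axes (default `TRUE`).
#' @return A ggplot object of the empirical degree distribution.
#' @export
plot_degree_distribution <- function(g, log_log = TRUE) {
  k <- igraph::degree(g)
  df <- as_tibble(table(k)) |>
    mutate(k = as.integer(.data$k), p = .data$n / sum(.data$n))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$p)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "degree k", y = "P(k)") +
    ggplot2::theme_minimal()
  if (log_log) p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  p
}
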