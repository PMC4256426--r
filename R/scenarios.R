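# Closed-form payoffs for an isolated mutual-best-friend pair in the
# best-friend-investment limit (alpha -> Inf).
#
# When investment preference is extreme, each cooperator sends its whole
# budget c*k to its best friend, so the pair's fate is decided by the four
# strategy portfolios CC, CD, DC, DD alone; third parties contribute
# nothing to either member.

#' Closed-form pair payoffs in the best-friend limit
#'
#' For a mutual-best-friend pair with degrees `k_i`, `k_j` under extreme
#' investment preference, each cooperating member sends its entire budget
#' `c * k` to the partner, who receives it scaled to benefit `b * k`. The
#' four portfolios give:
#' \describe{
#'   \item{CC}{`P_i = b k_j - c k_i`, `P_j = b k_i - c k_j`; total `(b - c)(k_i + k_j)`.}
#'   \item{CD}{(`i` cooperates) `P_i = -c k_i`, `P_j = b k_i`.}
#'   \item{DC}{mirror of CD.}
#'   \item{DD}{both zero.}
#' }
#' With `k_i = k_j = k` the totals order as
#' `CC = 2k(b - c) > CD = DC = k(b - c) > DD = 0`: a cooperating pair is the
#' highest-earning configuration, the ally that converts its neighbors.
#'
#' @param k_i,k_j Degrees of the two members, `>= 1`.
#' @param b,c Donation-game benefit and cost, `0 < c < b`.
#' @return A tibble of class `pair_scenarios` with one row per portfolio:
#'   columns `portfolio` (`"CC"`, `"CD"`, `"DC"`, `"DD"`), `payoff_i`,
#'   `payoff_j`, `total`; attributes record the inputs.
#' @examples
#' pair_scenario_payoffs(k_i = 4, k_j = 4, b = 1, c = 0.5)
#' @export
pair_scenario_payoffs <- function(k_i, k_j, b, c) {
  if (k_i < 1 || k_j < 1) abort("degrees must be >= 1")
  if (c <= 0 || b <= c) abort("need 0 < c < b")
  out <- tibble(
    portfolio = c("CC", "CD", "DC", "DD"),
    payoff_i = c(b * k_j - c * k_i, -c * k_i, b * k_j, 0),
    payoff_j = c(b * k_i - c * k_j, b * k_i, -c * k_j, 0)
  ) |>
    mutate(total = .data$payoff_i + .data$payoff_j)
  attr(out, "inputs") <- list(k_i = k_i, k_j = k_j, b = b, c = c)
  class(out) <- c("pair_scenarios", class(out))
  out
}

#' Pair-scenario totals over a grid of degrees and costs
#'
#' Convenience grid for exploring when the cooperating pair dominates:
#' evaluates [pair_scenario_payoffs()] at `k_i = k_j = k` for every
#' combination of `k` and `c` and returns the long table of totals.
#'
#' @param k Vector of degrees.
#' @param c Vector of costs.
#' @param b Benefit (scalar), `b > max(c)`.
#' @return A tibble with columns `k`, `c`, `portfolio`, `total`.
#' @export
pair_scenario_grid <- function(k, c, b = 1) {
  tidyr::expand_grid(k = k, c = c) |>
    mutate(res = purrr::map2(k, c, \(kk, cc) {
      pair_scenario_payoffs(kk, kk, b, cc) |>
        select("portfolio", "total")
    })) |>
    tidyr::unnest("res")
}
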