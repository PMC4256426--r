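---
title: "Relation-weighted donation games: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relation-weighted donation games: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiegame)
```

## The question

In the classical networked prisoner's dilemma every friendship is the same:
a cooperator splits its investment equally over its neighbors. Real social
ties are not interchangeable — people give far more to close friends than
to nodding acquaintances — and the strength of a tie is well approximated
by how much the two endpoints' friendship circles overlap. `tiegame`
implements a donation game in which cooperators allocate investment across
neighbors in proportion to tie strength raised to a preference exponent,
and asks when that relational preference rescues cooperation that equal
splitting cannot sustain.

## Tie strength

For an edge $(i, j)$ with degrees $k_i, k_j$ and $n_{ij}$ common
neighbors, the strength is the topological overlap

$$w_{ij} = \frac{n_{ij}}{(k_i - 1) + (k_j - 1) - n_{ij}} \in [0, 1],$$

the fraction of the two players' *other* relations that they share.
Connected pairs with no common neighbors are not given strength zero —
they do have a friendship — but a strictly positive floor. Two floor
policies are provided:

* `min_positive` (default): the smallest positive overlap present in the
  graph. This keeps floored edges strictly weakest under any
  $\alpha > 0$ without introducing an arbitrary scale.
* `fixed(epsilon)`: a constant, for sensitivity checks (`1e-6` default).

A plain Jaccard variant (`method = "jaccard"`) is available for
sensitivity analysis; all results in the package use the topological
overlap.

## Payoffs

A cooperator $x$ with degree $k_x$ spends $c\,k_x$ per round, splitting it
as $a_{x \to j} = c\,k_x\, w_{xj}^{\alpha} / \sum_z w_{xz}^{\alpha}$. Each
unit of investment delivers benefit $b/c$ to its recipient, so neighbor
$j$ receives $b\,k_x\, w_{xj}^{\alpha} / \sum_z w_{xz}^{\alpha}$, and

$$P_x = \sum_{y \in \Omega_x^C} b\,k_y\,
   \frac{w_{yx}^{\alpha}}{\sum_{z} w_{yz}^{\alpha}}
   \;-\; [x \in C]\; c\,k_x,$$

where $\Omega_x^C$ are $x$'s cooperating neighbors. Two identities pin the
construction down and are enforced by tests:

* $\alpha = 0$ recovers the classical donation game exactly — every
  neighbor of a cooperator receives $b$;
* $\sum_x P_x = (b - c) \sum_{x \in C} k_x$ for every graph, profile, and
  $\alpha$ (budget conservation).

On the two-hub toy (`toy_two_hubs(3)`, hubs cooperating, $b = 1$,
$c = 0.5$) the payoffs are $(-1, -1, 2, 2, 2)$ at $\alpha = 0$ and
$(2, 2, 0, 0, 0)$ at $\alpha \to \infty$: equal splitting hands the game
to the defecting leaves, while best-friend investment makes the hub pair
untouchable.

## Dynamics

Strategies evolve by synchronous Fermi imitation: each generation, every
player $x$ draws one neighbor $y$ uniformly and adopts $y$'s strategy with
probability $1 / (1 + \exp((P_x - P_y)/K))$, all updates applied from the
same payoff snapshot. All-C and all-D are absorbing. The equilibrium
cooperator fraction $f_c$ is the mean over a sampling window after a
transient.

### Parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `b` | benefit per unit classical investment | 1 | payoff scale is arbitrary; only $c/b$ matters |
| `c` | cost per neighbor ($0 < c < b$) | 0.3 | mid-range dilemma strength used in the reference sweeps |
| `alpha` | preference exponent ($\ge 0$ or `Inf`) | 1 | the quantity under study; `Inf` = best-friend-only |
| `K` | Fermi selection noise | 0.1 | the standard strong-selection choice in this literature |
| `transient`/`window` | burn-in / averaging generations | 2000 / 500 | equilibria in our problem sizes (≤ 500 nodes) stabilize well before 2000 generations; the classical long protocol (10000/1000) is available via the CLI's `--long-protocol` |

### Numerical choices

* $\alpha = \infty$ is computed exactly as a uniform split over the
  argmax-strength neighbor set, never via a large exponent; finite
  $\alpha$ scales strengths by their maximum before exponentiation so
  $w^\alpha$ cannot underflow to an all-zero weight vector. Payoffs at
  $\alpha = 40$ agree with the exact infinite mode to $10^{-6}$ on the toy.
* The Fermi exponent is clamped at $\pm 745$ so extreme payoff gaps
  saturate at probability 0/1 instead of overflowing.
* Best-friend ties: `argmax_set` (all maximizers) is the default for
  reciprocity counting, with `strict` (unique maximizer or nothing)
  available; the distinction matters on graphs with many exactly equal
  strengths (see below).
* Runs absorbing at all-C/all-D exit early and pad the constant tail, so
  window averages are identical to a full iteration.
* Reproducibility: one seeded RNG per run; each generation consumes two
  `runif(n)` vectors in node-id order (neighbor choice, then imitation
  flip). Identical (graph, parameters, seed) gives bit-identical traces.
* Replicate $r$ of an experiment uses seed `base_seed + r - 1`, so any
  table row can be reproduced in isolation.

## Synthetic networks and what they can show

Real friendship networks combine three features: high clustering, diverse
tie strengths *within* each neighborhood, and reciprocal unique best
friendships often anchored on well-connected pairs. No single classical
generator reproduces all three, and the package's families are chosen to
separate them:

* `barabasi_albert()` / `barabasi_albert_matched()`: the negative control.
  Locally tree-like, so almost all ties sit at the floor; investment
  preference has nothing to act on and $\alpha$ has no significant effect
  on $f_c$. The construction follows the standard repeated-nodes
  preferential-attachment scheme with exactly $m(n-m)$ edges.
* `clustered_graph()` (relaxed caveman): cliques sparsely rewired. It has
  high clustering and a spread-out strength *distribution*, but inside a
  clique every tie has the same strength, so argmax sets are large,
  best-friend investment is diluted, and "mutual best pairs" counted under
  `argmax_set` are mostly artifacts of exact ties. On this family strong
  preference does **not** rescue cooperation at dense mean degrees: a
  cooperating pair earns at most $(b-c)\,k_{\text{pair}}$ while a defector
  harvesting a single converted neighbor earns up to $b\,k$, and with
  community size $s$ the pair degree is capped at $s - 1$ — once the mean
  degree approaches that cap, $(b-c)k_{\text{pair}} < b\,\bar{k}$ and the
  allies are always outearned. Degree heterogeneity *beyond* the community
  scale, which cliques cannot provide, is a necessary ingredient.
* `community_hubs_graph()`: the relationally diverse clustered family.
  Each community has two hubs adjacent to each other and to all members
  (their neighborhoods coincide, so the hub-hub tie has strength 1 — the
  community-level version of the two-hub toy), with leaves wired in a
  sparse ring. Hubs dominate their neighborhoods in degree, best
  friendships are unique and reciprocal, and strong preference produces
  the headline effect: on a 500-node graph at $c = 0.3$ the median
  equilibrium $f_c$ rises from about 0.04 at $\alpha = 1$ to above 0.45
  at $\alpha \ge 4$, while $\alpha = 0$ sits near 0.14 (sparser graphs
  retain some classical cooperation; the non-monotonic dip at weak
  preference is real: mild concentration wastes investment on
  non-reciprocating ties without yet creating unbeatable allies).
* `toy_two_hubs()`: the exact five-node fixture for closed-form checks.

What passing tests on these families do **not** show: that the effect has
the magnitude reported for empirical friendship networks. The empirical
graphs have hub degrees far above the mean (hundreds vs. a mean of
16–44), which makes cooperating hub pairs dramatically stronger than any
synthetic family of bounded community size can emulate; the package's
generators demonstrate the mechanism and its direction, not the empirical
effect size. The Facebook-style datasets themselves are not redistributed
with the package; `read_adjacency_matrix()` (dense text or MatrixMarket)
and `read_edge_list()` load them if present locally.

## Pair scenarios in the best-friend limit

For a mutual-best-friend pair $(i, j)$ under $\alpha \to \infty$, each
cooperating member sends its whole budget to the partner and third parties
contribute nothing, giving closed forms per portfolio: CC earns
$P_i = b k_j - c k_i$, $P_j = b k_i - c k_j$ (total $(b-c)(k_i + k_j)$);
CD costs the cooperator $c k_i$ and hands the defector $b k_i$; DD earns
zero. With $k_i = k_j = k$ the totals order
$2k(b-c) > k(b-c) > 0$ — the cooperating pair is the highest-earning
configuration, which is why a few seeded reciprocal allies can convert
their neighborhoods. `pair_scenario_payoffs()` returns the table;
consistency with the simulator on the toy fixture is enforced exactly.

## Known limitations

* The pair analysis treats the pair in isolation; on graphs where argmax
  sets are not singletons the $\alpha \to \infty$ allocation splits and
  the closed forms do not apply (use `best_friends(..., "strict")` to
  identify genuinely exclusive pairs).
* Tie strengths are static: the network does not co-evolve with play.
* Synchronous updating only; no mutation, so absorbing states are final.
* Equilibria on finite windows are estimates; all sweep assertions in the
  package use medians over ≥ 8 independent seeds.
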