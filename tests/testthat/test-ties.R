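test_that("overlap matches hand-computed values on small fixtures", {
  k3 <- igraph::make_full_graph(3)
  expect_equal(tie_overlap(k3, 1, 2), 1.0)

  # 4-cycle a-b-c-d-a plus chord a-c; edge (a, b): n = 1, k_a = 3, k_b = 2
  g <- igraph::make_graph(~ a - b, b - c, c - d, d - a, a - c)
  expect_equal(tie_overlap(g, 1, 2), 0.5)

  path <- igraph::make_graph(~ 1 - 2, 2 - 3)
  expect_equal(tie_overlap(path, 1, 2), 0)

  expect_error(tie_overlap(path, 1, 3), "not an edge")
})

test_that("overlap agrees with brute-force set intersection on random graphs", {
  for (seed in 1:20) {
    g <- random_test_graph(sample(5:30, 1), 0.3, seed)
    el <- igraph::as_edgelist(g, names = FALSE)
    for (r in seq_len(nrow(el))) {
      expect_equal(tie_overlap(g, el[r, 1], el[r, 2]),
                   oracle_overlap(g, el[r, 1], el[r, 2]))
    }
  }
})

test_that("tie tables are symmetric, in range, and floor zero overlaps", {
  for (seed in 1:10) {
    g <- random_test_graph(20, 0.2, seed)
    ties <- compute_ties(g)
    expect_equal(nrow(ties), igraph::ecount(g))
    expect_true(all(ties$strength > 0 & ties$strength <= 1))
    expect_true(all(ties$strength[ties$n_common == 0] == attr(ties, "floor_value")))
    expect_true(all(ties$floored == (ties$n_common == 0)))
    # symmetric by construction: each unordered edge appears exactly once
    expect_false(any(duplicated(ties[, c("from", "to")])))
    expect_true(all(ties$from < ties$to))
  }
})

test_that("floor policies behave as documented", {
  star <- igraph::make_star(4, mode = "undirected")  # K_{1,3}: all overlaps 0
  fixed <- compute_ties(star, floor_policy = "fixed", epsilon = 1e-6)
  expect_true(all(fixed$strength == 1e-6))
  expect_equal(attr(fixed, "floor_value"), 1e-6)

  # min_positive falls back to epsilon when every overlap is zero
  minp <- compute_ties(star, floor_policy = "min_positive", epsilon = 1e-4)
  expect_true(all(minp$strength == 1e-4))

  # with positive overlaps present, the floor is the smallest of them
  g <- toy_two_hubs(3)
  g <- igraph::add_vertices(g, 1)
  g <- igraph::add_edges(g, c(6, 3))   # pendant: edge (3, 6) has no overlap
  ties <- compute_ties(g)
  expect_equal(attr(ties, "floor_value"), 1 / 4)  # hub-leaf overlap drops to 1/4
  expect_error(compute_ties(g, floor_policy = "fixed", epsilon = 0), "epsilon")
})

test_that("two-hub toy strengths match the closed form", {
  ties <- compute_ties(toy_two_hubs(3))
  hub_hub <- ties[ties$from == 1 & ties$to == 2, ]
  expect_equal(hub_hub$strength, 1.0)
  others <- ties[!(ties$from == 1 & ties$to == 2), ]
  expect_equal(others$strength, rep(1 / 3, 6))

  k5 <- compute_ties(igraph::make_full_graph(5))
  expect_true(all(k5$strength == 1))
})

test_that("adding a common neighbor never decreases overlap", {
  # edge (1, 2) in a graph where 1 and 2 have fixed side-attachments
  for (extra in 0:3) {
    g <- igraph::make_empty_graph(7 + extra, directed = FALSE)
    g <- igraph::add_edges(g, c(1, 2, 1, 3, 2, 4, 1, 5, 2, 5))
    prev <- tie_overlap(g, 1, 2)
    if (extra > 0) {
      for (z in seq_len(extra)) {
        g <- igraph::add_edges(g, c(1, 5 + z, 2, 5 + z))
        cur <- tie_overlap(g, 1, 2)
        expect_gte(cur, prev)
        prev <- cur
      }
    }
  }
})

test_that("jaccard variant uses full neighbor sets", {
  k3 <- igraph::make_full_graph(3)
  # edge (1,2): common 1, |N(1) u N(2)| = 3
  expect_equal(tie_overlap(k3, 1, 2, method = "jaccard"), 1 / 3)
  ties <- compute_ties(k3, method = "jaccard")
  expect_true(all(ties$overlap == 1 / 3))
})

test_that("strength histograms bin correctly and conserve mass", {
  k5 <- compute_ties(igraph::make_full_graph(5))
  h <- strength_histogram(k5, 10)
  expect_equal(sum(h$count), 10)
  expect_equal(h$count[10], 10)                  # all strength 1 in last bin

  star <- compute_ties(igraph::make_star(4, mode = "undirected"),
                       floor_policy = "fixed", epsilon = 1e-6)
  h2 <- strength_histogram(star, 10)
  expect_equal(h2$count[1], 3)                   # floored mass in first bin
  expect_equal(sum(h2$count), 3)

  toy <- compute_ties(toy_two_hubs(3))
  expect_equal(sum(strength_histogram(toy, 7)$count), 7)
  expect_error(strength_histogram(toy, 0), "n_bins")
})

test_that("best friends respect tie policies", {
  toy <- compute_ties(toy_two_hubs(3))
  expect_equal(best_friends(toy, 1, "argmax_set"), 2L)
  expect_equal(best_friends(toy, 1, "strict"), 2L)

  star <- compute_ties(igraph::make_star(4, mode = "undirected"))
  expect_equal(best_friends(star, 1, "argmax_set"), c(2L, 3L, 4L))
  expect_length(best_friends(star, 1, "strict"), 0)
  expect_equal(best_friends(star, 2, "argmax_set"), 1L)  # single neighbor
})

test_that("mutual-best-pair counting matches hand enumeration", {
  toy <- compute_ties(toy_two_hubs(3))
  expect_equal(count_mutual_best_pairs(toy), 1)
  expect_equal(mutual_best_pairs(toy)$from, 1L)
  expect_equal(mutual_best_pairs(toy)$to, 2L)

  # two disjoint edges: each endpoint's only neighbor -> 2 pairs
  g2 <- igraph::make_empty_graph(4, directed = FALSE)
  g2 <- igraph::add_edges(g2, c(1, 2, 3, 4))
  t2 <- compute_ties(g2)
  expect_equal(count_mutual_best_pairs(t2), 2)

  # K4: every edge is mutual under argmax_set, none under strict
  k4 <- compute_ties(igraph::make_full_graph(4))
  expect_equal(count_mutual_best_pairs(k4, "argmax_set"), 6)
  expect_equal(count_mutual_best_pairs(k4, "strict"), 0)
})

test_that("preferential-attachment graphs have more floored ties than clustered", {
  for (seed in 1:5) {
    cl <- clustered_graph(300, 15, 0.1, seed = seed)
    ba <- barabasi_albert_matched(igraph::vcount(cl), igraph::ecount(cl),
                                  seed = seed)
    f_ba <- floored_fraction(compute_ties(ba))
    f_cl <- floored_fraction(compute_ties(cl))
    expect_gt(f_ba, f_cl)
    # distributional contrast: mass below 0.1
    frac_low <- function(t) mean(t$strength < 0.1)
    expect_gt(frac_low(compute_ties(ba)), frac_low(compute_ties(cl)))
  }
})

test_that("tie tables write as three-column TSV", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ties(compute_ties(toy_two_hubs(3)), f)
  back <- utils::read.delim(f)
  expect_equal(names(back), c("from", "to", "strength"))
  expect_equal(nrow(back), 7)
})
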