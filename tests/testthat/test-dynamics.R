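test_that("fermi probability matches the closed form and is monotone", {
  expect_equal(fermi_probability(0.7, 0.7, 0.1), 0.5)
  expect_equal(fermi_probability(0, 1, 0.1), 1 / (1 + exp(-10)))
  expect_equal(fermi_probability(1, 0, 0.1), 1 / (1 + exp(10)))
  # extreme gaps saturate without overflow warnings
  expect_equal(fermi_probability(-1e6, 1e6, 0.01), 1)
  expect_equal(fermi_probability(1e6, -1e6, 0.01), 0)
  # monotone decreasing in p_x - p_y
  gaps <- seq(-5, 5, by = 0.5)
  probs <- fermi_probability(gaps, 0, 0.5)
  expect_true(all(diff(probs) < 0))
  expect_error(fermi_probability(0, 1, 0), "K")
})

test_that("homogeneous populations are absorbing states", {
  g <- random_test_graph(12, 0.3, 3)
  ties <- compute_ties(g)
  p <- game_params(c = 0.4, alpha = 1)
  for (s0 in list(rep("D", 12), rep("C", 12))) {
    for (i in 1:5) expect_equal(generation_step(g, ties, s0, p), s0)
  }
})

test_that("single-flip probability matches Monte-Carlo frequency", {
  g <- igraph::make_empty_graph(2, directed = FALSE)
  g <- igraph::add_edges(g, c(1, 2))
  ties <- compute_ties(g)
  p <- game_params(b = 1, c = 0.5, alpha = 1, K = 1)
  # payoffs (-c, b): the defector imitates with prob 1/(1+exp((b+c)/K))
  theory <- 1 / (1 + exp((p$b + p$c) / p$K))
  withr::local_seed(7)
  draws <- 20000
  flips <- vapply(seq_len(draws), function(i) {
    generation_step(g, ties, c("C", "D"), p)[2] == "C"
  }, logical(1))
  expect_equal(mean(flips), theory,
               tolerance = 4 * sqrt(theory * (1 - theory) / draws) / theory)
})

test_that("runs are bit-for-bit reproducible from the seed", {
  g <- clustered_graph(100, 10, 0.1, seed = 5)
  ties <- compute_ties(g)
  p <- game_params(c = 0.2, alpha = 2)
  init <- init_random_half(g, seed = 9)
  t1 <- run_evolution(g, ties, p, init, transient = 60, window = 20, seed = 11)
  t2 <- run_evolution(g, ties, p, init, transient = 60, window = 20, seed = 11)
  expect_identical(t1$trace, t2$trace)
  expect_identical(t1$equilibrium_f_c, t2$equilibrium_f_c)
  t3 <- run_evolution(g, ties, p, init, transient = 60, window = 20, seed = 12)
  expect_false(identical(t1$trace, t3$trace))
})

test_that("all-defector initial conditions absorb immediately", {
  g <- toy_two_hubs(3)
  ties <- compute_ties(g)
  tr <- run_evolution(g, ties, game_params(c = 0.5, alpha = 1),
                      rep("D", 5), transient = 10, window = 5, seed = 1)
  expect_equal(tr$equilibrium_f_c, 0)
  expect_equal(tr$absorbed_at, 0L)
  expect_true(all(tr$trace$f_c == 0))
  expect_equal(nrow(tr$trace), 16)   # padded to transient + window + 1
})

test_that("traces stay constant after absorption and f_c stays in [0, 1]", {
  g <- clustered_graph(60, 10, 0.1, seed = 2)
  ties <- compute_ties(g)
  tr <- run_evolution(g, ties, game_params(c = 0.45, alpha = 0),
                      init_random_half(g, seed = 3),
                      transient = 300, window = 100, seed = 3)
  f <- tr$trace$f_c
  expect_true(all(f >= 0 & f <= 1))
  if (!is.na(tr$absorbed_at)) {
    tail_vals <- f[(tr$absorbed_at + 1):length(f)]
    expect_true(all(tail_vals == tail_vals[1]))
  }
})

test_that("seeded hub pairs take over the two-hub toy under extreme preference", {
  g <- toy_two_hubs(3)
  ties <- compute_ties(g)
  p <- game_params(b = 1, c = 0.5, alpha = Inf, K = 0.1)
  eq <- vapply(1:40, function(s) {
    run_evolution(g, ties, p, init_seeded_pairs(g, ties, 1, seed = s),
                  transient = 100, window = 20, seed = s)$equilibrium_f_c
  }, numeric(1))
  expect_gte(mean(eq == 1), 0.95)
})

test_that("random-half initialization places exactly floor(N/2) cooperators", {
  for (n in c(10, 769, 11)) {
    g <- igraph::make_ring(n)
    s <- init_random_half(g, seed = 1)
    expect_equal(sum(s == "C"), n %/% 2)
  }
  g <- igraph::make_ring(40)
  s1 <- init_random_half(g, seed = 1)
  s2 <- init_random_half(g, seed = 2)
  expect_false(identical(s1, s2))
  expect_equal(sum(s1 == "C"), sum(s2 == "C"))
})

test_that("seeded-pair initialization marks exactly the chosen pairs", {
  g <- toy_two_hubs(3)
  ties <- compute_ties(g)
  s <- init_seeded_pairs(g, ties, 1, seed = 1)
  expect_equal(which(s == "C"), c(1L, 2L))   # only mutual pair: the hubs
  expect_equal(init_seeded_pairs(g, ties, 0, seed = 1), rep("D", 5))
  expect_error(init_seeded_pairs(g, ties, 2, seed = 1), "only 1")
})

test_that("classical equal-split investment suppresses cooperation on dense clustered graphs", {
  g <- clustered_graph(400, 20, 0.1, seed = 2)  # mean degree ~19
  ties <- compute_ties(g)
  p <- game_params(b = 1, c = 0.1, alpha = 0, K = 0.1)
  eq <- vapply(1:10, function(s) {
    run_evolution(g, ties, p, init_random_half(g, seed = s),
                  transient = 500, window = 100, seed = s)$equilibrium_f_c
  }, numeric(1))
  expect_lt(median(eq), 0.05)
})

test_that("strong preference for best friends rescues cooperation on hub communities", {
  g <- community_hubs_graph(500, 20, rewire_p = 0.1, seed = 2)
  ties <- compute_ties(g)
  med <- vapply(c(1, 4), function(a) {
    p <- game_params(b = 1, c = 0.3, alpha = a, K = 0.1)
    median(vapply(1:8, function(s) {
      run_evolution(g, ties, p, init_random_half(g, seed = s),
                    transient = 2000, window = 500, seed = s)$equilibrium_f_c
    }, numeric(1)))
  }, numeric(1))
  expect_lt(med[1], 0.2)
  expect_gt(med[2], 0.35)
  expect_gt(med[2] - med[1], 0.2)
})

test_that("traces serialize with metadata sidecar", {
  g <- toy_two_hubs(3)
  ties <- compute_ties(g)
  tr <- run_evolution(g, ties, game_params(c = 0.5, alpha = Inf),
                      init_seeded_pairs(g, ties, 1, seed = 1),
                      transient = 20, window = 10, seed = 4)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_trace(tr, f)
  back <- utils::read.delim(f)
  expect_equal(nrow(back), 31)
  meta <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(meta$seed, 4)
  expect_equal(meta$params$K, 0.1)
})

test_that("tidy, glance, and autoplot expose run results", {
  g <- toy_two_hubs(3)
  ties <- compute_ties(g)
  tr <- run_evolution(g, ties, game_params(c = 0.5, alpha = 2),
                      init_random_half(g, seed = 1),
                      transient = 30, window = 10, seed = 2)
  td <- tidy(tr)
  expect_equal(names(td), c("generation", "f_c", "seed", "alpha", "c"))
  expect_equal(nrow(td), 41)
  gl <- glance(tr)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$alpha, 2)
  expect_s3_class(autoplot(tr), "ggplot")
})
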