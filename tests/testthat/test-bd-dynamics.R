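fig1 <- make_fig1_graph()

test_that("mutant death rate is degree over average degree", {
  expect_equal(unname(mutant_death_rate(fig1$graph, c(2, 6, 10))),
               c(2 / 3, 2 / 3, 5 / 3))
  # regular graphs: rate 1 everywhere
  expect_equal(unname(mutant_death_rate(make_ring_lattice(10, 4))), rep(1, 10))
  expect_equal(unname(mutant_death_rate(make_complete(5))), rep(1, 5))
  # average over nodes is exactly one on any graph
  for (g in list(fig1$graph, make_star(9), make_scale_free(64, 2.7, seed = 4)))
    expect_equal(mean(mutant_death_rate(g)), 1)
  expect_error(mutant_death_rate(fig1$graph, 13), "unknown node")
})

test_that("death-selection probabilities reproduce the worked example", {
  s <- population_state(fig1$graph, fig1$mutants)
  p <- death_selection_probs(fig1$graph, s, 11)
  expect_equal(p[as.character(c(1, 2, 4, 6, 7, 10))],
               c(`1` = 1/6, `2` = 1/9, `4` = 1/6, `6` = 1/9, `7` = 1/6,
                 `10` = 5/18))
  expect_equal(sum(p), 1)
})

test_that("death selection is uniform over all-wild neighbourhoods and trivial for leaves", {
  g <- make_complete(6)
  s <- population_state(g, integer(0))
  expect_equal(unname(death_selection_probs(g, s, 3)), rep(1 / 5, 5))

  star <- make_star(5)
  s <- population_state(star, c(1L, 4L))  # core mutant: rate (n+1)/2, irrelevant
  p <- death_selection_probs(star, s, 2)  # a leaf reproduces
  expect_equal(unname(p), 1)
  expect_equal(names(p), "1")
})

test_that("selection probabilities sum to one across random states", {
  set.seed(99)
  g <- make_scale_free(64, 2.8, seed = 12)
  for (rep in 1:25) {
    s <- population_state(g, sample.int(64, sample.int(63, 1)))
    node <- sample.int(64, 1)
    expect_equal(sum(death_selection_probs(g, s, node)), 1, tolerance = 1e-12)
  }
})

test_that("bd_step replaces one neighbour and respects absorption", {
  g <- make_complete(2)
  set.seed(1)
  out <- replicate(50, {
    s2 <- bd_step(g, population_state(g, 1L))
    sum(s2)
  })
  expect_setequal(unique(out), c(0L, 2L))   # K2 absorbs in one step

  s <- population_state(fig1$graph, fig1$mutants)
  set.seed(2)
  s2 <- bd_step(fig1$graph, s)
  expect_true(abs(attr(s2, "mutant_count") - 3L) <= 1L)
  expect_equal(attr(s2, "mutant_count"), sum(s2 == 1L))

  expect_error(bd_step(g, population_state(g, 1:2)), "absorbing")
  expect_error(bd_step(g, population_state(g, integer(0))), "absorbing")
})

test_that("forced-reproducer victim frequencies match the exact distribution", {
  s <- population_state(fig1$graph, fig1$mutants)
  p <- death_selection_probs(fig1$graph, s, 11)
  set.seed(31)
  n <- 2e4
  flipped <- vapply(seq_len(n), function(.) {
    s2 <- bd_step(fig1$graph, s, reproducer = 11L)
    idx <- which(as.integer(s2) != as.integer(s))
    if (length(idx)) idx else 0L          # 0 = same-label copy, no flip
  }, integer(1))
  # node 11 is wild type, so only mutant victims (2, 6, 10) change label
  for (j in c(2, 6, 10)) {
    expect_within_se(mean(flipped == j), p[[as.character(j)]], n)
  }
  expect_within_se(mean(flipped == 0), 1/6 + 1/6 + 1/6, n)
})

test_that("run_to_fixation absorbs and reports both outcomes on tiny graphs", {
  g <- make_star(2)
  res <- sapply(1:60, function(s) {
    set.seed(s); run_to_fixation(g, initial_mutant = 2L)$fixed
  })
  expect_setequal(unique(res), c(TRUE, FALSE))
  set.seed(3)
  r <- run_to_fixation(make_complete(2))
  expect_gte(r$steps, 1)
  expect_error(run_to_fixation(make_complete(3), max_steps = 0), "cap")
  expect_error(run_to_fixation(igraph::make_empty_graph(1, directed = FALSE)),
               "at least 2")
})

test_that("estimates are reproducible from the seed, step counts included", {
  g <- make_small_world(30, 4, 0.5, seed = 8)
  a <- estimate_fixation_probability(g, 500, seed = 77)
  b <- estimate_fixation_probability(g, 500, seed = 77)
  expect_identical(a, b)
  gen <- function() make_small_world(30, 4, 0.5)
  c1 <- estimate_fixation_probability(gen, 200, n_graphs = 3, seed = 5)
  c2 <- estimate_fixation_probability(gen, 200, n_graphs = 3, seed = 5)
  expect_identical(c1, c2)
  expect_equal(c1$runs, 600)
  expect_false(is.na(c1$sd_across_graphs))
})

test_that("complete-graph estimate sits at the Moran value", {
  e <- estimate_fixation_probability(make_complete(8), 2e4, seed = 123)
  expect_within_se(e$probability, 1 / 8, e$runs)
})

test_that("Monte Carlo agrees with the exact oracle on small graphs", {
  battery <- list(make_star(4), igraph::make_ring(6), make_path(5),
                  fig1$graph)
  exact <- lapply(battery, exact_fixation_markov)
  for (b in seq_along(battery)) {
    g <- battery[[b]]
    e <- estimate_fixation_probability(g, 2e4, seed = 400 + b)
    target <- mean(exact[[b]])   # uniform start averages node-wise values
    expect_within_se(e$probability, target, e$runs)
  }
})
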