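test_that("star death rates follow the degree-coupled rule", {
  r <- star_death_rates(8)
  expect_equal(r$d_core, 9 / 2)
  expect_equal(r$d_leaf, 9 / 16)
  r1 <- star_death_rates(1)
  expect_equal(r1$d_core, 1)
  expect_equal(r1$d_leaf, 1)
  # population-average mutant death rate is one for every n
  for (n in 1:40) {
    r <- star_death_rates(n)
    expect_equal((n * r$d_leaf + r$d_core) / (n + 1), 1)
  }
  expect_error(star_death_rates(0), "positive")
})

test_that("transition probabilities conserve probability and absorb at the ends", {
  for (n in c(2, 5, 9)) {
    for (i in 0:n) {
      for (v in c(FALSE, TRUE)) {
        w <- star_transition_probs(n, i, v)
        expect_equal(sum(w), 1)
        expect_true(all(w >= 0))
      }
    }
    w00 <- star_transition_probs(n, 0, FALSE)   # all wild type
    expect_equal(unname(w00), c(0, 0, 1))
    wn1 <- star_transition_probs(n, n, TRUE)    # all mutant
    expect_equal(unname(wn1), c(0, 0, 1))
  }
  # hand substitution at n = 2, i = 1, core wild, d = 3/4
  w <- star_transition_probs(2, 1, FALSE)
  expect_equal(w[["alpha"]], 1 / 7)
  expect_equal(w[["beta"]], 1 / 3)
  expect_error(star_transition_probs(3, 4, TRUE), "0..n")
})

test_that("conditional jump parameters normalize and simplify correctly", {
  for (n in c(3, 6, 11)) {
    d <- star_death_rates(n)$d_leaf
    for (i in 1:(n - 1)) {
      p <- star_p_parameters(n, i)
      expect_equal(p[["P_left"]] + p[["P_down"]], 1)
      expect_equal(p[["P_right"]] + p[["P_up"]], 1)
      # algebraic simplification of P_right
      expect_equal(p[["P_right"]], 1 / (1 + i * d + n - i))
    }
  }
  p0 <- star_p_parameters(2, 0)
  expect_equal(p0[["P_right"]], 1 / 3)
  expect_true(is.na(p0[["P_left"]]))       # (0,0) cannot jump
})

test_that("the 2x2 recursion reproduces the coupled fixation equations", {
  n <- 5
  sol <- solve_star(n)
  d <- star_death_rates(n)$d_leaf
  # residuals of the scalar equations given the solved vectors
  for (i in 1:(n - 1)) {
    w1 <- star_transition_probs(n, i, TRUE)
    res1 <- w1[["alpha"]] * sol$pi1[i + 2] + w1[["beta"]] * sol$pi0[i + 1] +
      w1[["stay"]] * sol$pi1[i + 1] - sol$pi1[i + 1]
    w0 <- star_transition_probs(n, i, FALSE)
    res0 <- w0[["alpha"]] * sol$pi0[i] + w0[["beta"]] * sol$pi1[i + 1] +
      w0[["stay"]] * sol$pi0[i + 1] - sol$pi0[i + 1]
    expect_lt(abs(res1), 1e-12)
    expect_lt(abs(res0), 1e-12)
  }
  # X_i = A_i X_{i-1} holds entrywise
  for (i in 1:n) {
    X <- star_recursion_matrix(n, i) %*% c(sol$pi1[i], sol$pi0[i])
    expect_equal(as.numeric(X), c(sol$pi1[i + 1], sol$pi0[i + 1]),
                 tolerance = 1e-10)
  }
  # entries stay finite across a wide scan
  for (n2 in c(50, 200)) {
    for (i in seq_len(n2)) {
      expect_true(all(is.finite(star_recursion_matrix(n2, i))))
    }
  }
  expect_error(star_recursion_matrix(4, 0), "1..n")
})

test_that("both solve_star routes agree and satisfy the solution invariants", {
  for (n in c(1, 2, 5, 20, 100)) {
    a <- solve_star(n, method = "chain")
    b <- solve_star(n, method = "recursion")
    expect_lt(max(abs(a$pi0 - b$pi0), abs(a$pi1 - b$pi1)), 1e-10)
    expect_equal(a$pi0[1], 0)
    expect_equal(a$pi1[n + 1], 1, tolerance = 1e-12)
    expect_true(all(diff(a$pi0) >= -1e-12))
    expect_true(all(diff(a$pi1) >= -1e-12))
    expect_true(all(a$pi1 - a$pi0 >= -1e-12))
    expect_true(all(a$pi0 >= -1e-12 & a$pi0 <= 1 + 1e-12))
  }
})

test_that("solve_star matches the exhaustive oracle on small stars", {
  for (n in 2:8) {
    sol <- solve_star(n)
    v <- exact_fixation_markov(make_star(n))
    expect_lt(abs(sol$pi1[1] - v[[1]]), 1e-10)
    expect_lt(abs(sol$pi0[2] - v[[2]]), 1e-10)
  }
})

test_that("the core death rate never enters the dynamics", {
  # a leaf's only neighbour is the core, chosen with probability 1 whatever
  # its rate, so replacing d_core changes nothing
  for (n in c(3, 6)) {
    g <- make_star(n)
    base <- exact_fixation_markov(g)
    dm <- mutant_death_rate(g)
    dm[1] <- 17.5
    expect_equal(exact_fixation_markov(g, mutant_death = dm), base,
                 tolerance = 1e-12)
  }
})

test_that("leaf/core fixation ratio follows the closed form", {
  for (n in 2:50) {
    sol <- solve_star(n)
    expect_lt(abs(sol$pi0[2] / sol$pi1[1] - star_fixation_ratio(n)), 1e-9)
  }
  expect_equal(star_fixation_ratio(1), 1)  # K2 symmetry
})

test_that("core-start probability decreases in n and undercuts 1/(n+1)", {
  pi01 <- sapply(2:40, function(n) solve_star(n)$pi1[1])
  expect_true(all(diff(pi01) < 0))
  expect_true(all(pi01 < 1 / (3:41)))
})

test_that("leaf-start probability has its minimum at n = 5", {
  pi10 <- sapply(2:30, function(n) solve_star(n)$pi0[2])
  expect_equal((2:30)[which.min(pi10)], 5)
})

test_that("moran_fixation covers neutral and selective regimes", {
  expect_equal(moran_fixation(1, 1, 10), 1 / 10)
  expect_equal(moran_fixation(2, 1, 3), 1 / 7)
  expect_lt(moran_fixation(50, 1, 20), 1e-15)
  expect_equal(moran_fixation(1e-9, 1, 20), 1, tolerance = 1e-8)
  expect_error(moran_fixation(0, 1, 5), "positive")
  expect_error(moran_fixation(1, 1, 1), ">= 2")
})
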