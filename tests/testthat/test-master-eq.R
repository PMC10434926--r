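test_that("forward step reproduces hand recursions", {
  # isolated infectious node: pI decays by 1/D, mass moves to R
  iso <- epi_network(1, matrix(integer(0), ncol = 2))
  p <- probability_state(1, pI = 1)
  p1 <- forward_step(p, iso, 0.3, D = 4)
  expect_equal(unname(p1), matrix(c(0, 0.75, 0.25), 1))

  # all susceptible is a fixed point
  net <- path_network(4)
  p <- probability_state(4)
  expect_equal(forward_step(p, net, 0.5, Inf), p)

  # two-node edge, beta = 0.3, no recovery: hand recursion on node 2
  edge <- path_network(2)
  p <- probability_state(2, pI = c(1, 0))
  p1 <- forward_step(p, edge, 0.3, Inf)
  expect_equal(unname(p1[2, 2]), 0.3)
  p2 <- forward_step(p1, edge, 0.3, Inf)
  expect_equal(unname(p2[2, 2]), 1 - 0.7^2)

  expect_error(forward_step(probability_state(3), edge, 0.3, Inf), "matrix")
})

test_that("integration composes forward steps and returns intermediates", {
  net <- build_er(30, 3, seed = 301)
  p <- probability_state(30, pI = runif(30, 0, 0.2))
  beta <- runif(30, 0.1, 0.3)
  expect_equal(integrate_master(p, net, beta, 4, 0), list(p))
  out <- integrate_master(p, net, beta, 4, 2)
  expect_equal(out[[3]],
               forward_step(forward_step(p, net, beta, 4), net, beta, 4))
})

test_that("integrated marginals stay on the simplex and are monotone", {
  set.seed(302)
  net <- build_er(50, 4)
  p <- probability_state(50, pI = runif(50, 0, 0.3))
  states <- integrate_master(p, net, runif(50, 0.05, 0.4), 3, 8)
  for (s in states) {
    expect_true(all(s >= 0 & s <= 1))
    expect_equal(rowSums(s), rep(1, 50), tolerance = 1e-9)
  }
  arr <- simplify2array(states)
  expect_true(all(diff(t(arr[, 3, ])) >= -1e-12))   # pR non-decreasing
  expect_true(all(diff(t(arr[, 1, ])) <= 1e-12))    # pS non-increasing
})

test_that("master equations are exact at short horizons and boundedly biased later", {
  # exact joint-state DP oracle on a 4-node path, heterogeneous beta
  net <- path_network(4)
  beta <- c(0.3, 0.25, 0.2, 0.35)
  exact <- exact_sir_marginals(net, beta, D = 3, seeds = 1, T = 7)
  p <- probability_state(4, pI = c(1, 0, 0, 0))
  me <- integrate_master(p, net, beta, 3, 7)
  # horizons 1-2: the independence closure has not yet built up correlations
  for (d in 1:2)
    expect_equal(unname(me[[d + 1]]), unname(exact[, , d + 1]),
                 tolerance = 1e-12)
  # later horizons: the closure over-counts infection (temporal correlation
  # and echo effects), but the deviation stays bounded on this fixture
  err <- max(abs(simplify2array(me) - aperm(exact, c(1, 2, 3))))
  expect_lt(err, 0.15)
  # bias direction: the closure never underestimates cumulative infection
  expect_gte(sum(me[[8]][, 2:3]), sum(exact[, 2:3, 8]) - 1e-9)
})

test_that("conditional likelihoods are products of daily transition matrices", {
  expect_equal(conditional_likelihood(numeric(0), 4), diag(3),
               ignore_attr = TRUE)

  L <- conditional_likelihood(c(0.4, 0.1, 0.7), 4)
  expect_equal(unname(L[3, ]), c(0, 0, 1))          # R absorbing
  expect_equal(rowSums(L), rep(1, 3), ignore_attr = TRUE)

  # infectious start, zero hazard: geometric recovery
  L0 <- conditional_likelihood(rep(0, 5), 3)
  expect_equal(L0["I", "I"], (2 / 3)^5)
  expect_equal(L0["I", "R"], 1 - (2 / 3)^5)

  # time-varying hazards vs exhaustive path enumeration
  for (h in list(c(0.2, 0.5), c(0.9, 0.05, 0.3), runif(4))) {
    expect_equal(unname(conditional_likelihood(h, 3)),
                 chain_likelihood_oracle(h, 3), tolerance = 1e-12)
  }
  expect_error(conditional_likelihood(c(0.2, NA), 3), "missing")
})

test_that("the vectorized likelihood column agrees with the matrix product", {
  set.seed(303)
  for (m in c(1, 3, 6)) for (o in 1:3) {
    H <- matrix(runif(5 * m), 5, m)
    col <- ensir:::likelihood_column(H, 4, o)
    for (k in 1:5)
      expect_equal(col[k, ], unname(conditional_likelihood(H[k, ], 4)[, o]),
                   tolerance = 1e-12)
  }
})

test_that("hazards vanish without infectious neighbours and use the node's own beta", {
  net <- star_network(3)
  p <- probability_state(4)
  expect_equal(infection_hazard(p, net, 0.5), rep(0, 4))
  p[2, ] <- c(0, 1, 0)          # one infectious leaf
  beta <- c(0.4, 0.1, 0.1, 0.1)
  h <- infection_hazard(p, net, beta)
  expect_equal(h[1], 0.4)       # center uses its own susceptibility
  expect_equal(h[3], 0)         # leaves are not adjacent to the infectious leaf
})
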