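test_that("ensemble initialization draws the stated priors", {
  net <- build_er(50, 3, seed = 401)
  expect_error(inference_config(K = 1), "at least 2")
  expect_error(inference_config(var_floor = 0), "positive")

  set.seed(402)
  ens <- init_ensemble(net, inference_config(K = 10, p0 = 0))
  expect_true(all(ens$prob[, 1, ] == 1))        # p0 = 0: all susceptible

  expect_equal(inference_config()$K, 100)       # packaged ensemble size

  ens <- init_ensemble(net, inference_config(K = 200, beta_lo = 0.1,
                                             beta_hi = 0.3))
  expect_true(all(ens$beta >= 0.1 & ens$beta <= 0.3))
  se <- 0.2 / sqrt(12 * length(ens$beta))       # uniform sd / sqrt(n)
  expect_lt(abs(mean(ens$beta) - 0.2), 3 * se)
  expect_true(all(abs(rowSums(aperm(ens$prob, c(3, 1, 2)), dims = 2) - 1)
                  < 1e-12))
})

test_that("backward Bayes update matches hand calculations", {
  # flat likelihood: posterior = prior
  up <- bayes_backward_update(c(0.3, 0.5, 0.2), c(1, 1, 1))
  expect_equal(up$posterior, c(0.3, 0.5, 0.2))
  expect_equal(up$delta, c(0, 0, 0))

  # identity likelihood (same-day observation of I)
  up <- bayes_backward_update(c(0.4, 0.6, 0), c(0, 1, 0))
  expect_equal(up$posterior, c(0, 1, 0))

  # printed hand-Bayes example
  up <- bayes_backward_update(c(0.5, 0.5, 0), c(0.2, 0.8, 0.7))
  expect_equal(up$posterior, c(0.2, 0.8, 0))

  # impossible observation: least-impossible fallback with a warning
  expect_warning(
    up <- bayes_backward_update(c(1, 0, 0), c(0, 0.9, 0.1)),
    "impossible")
  expect_equal(up$posterior, c(0, 1, 0))

  # matrix form operates row-wise
  P <- rbind(c(0.5, 0.5, 0), c(0.4, 0.6, 0))
  upm <- bayes_backward_update(P, c(0.2, 0.8, 0.7))
  expect_equal(upm$posterior[1, ], c(0.2, 0.8, 0))
})

test_that("covariability adjustment is the cross-ensemble regression", {
  K <- 3
  delta <- rbind(c(0.1, -0.1, 0), c(-0.05, 0.05, 0), c(0.02, -0.02, 0))

  # neighbour constant across members: zero covariance, no change
  P_obs <- rbind(c(0.5, 0.5, 0), c(0.3, 0.7, 0), c(0.6, 0.4, 0))
  P_nb <- matrix(rep(c(0.8, 0.2, 0), each = K), K)
  expect_equal(covariability_adjust(P_obs, P_nb, delta), P_nb)

  # neighbour identical to observed node: C = 1, deltas copied
  out <- covariability_adjust(P_obs, P_obs, delta)
  expect_equal(out, P_obs + delta)

  # 3-member hand ensemble: regression coefficient computed by the
  # covariance/variance formula directly, state by state
  P_nb2 <- rbind(c(0.7, 0.3, 0), c(0.5, 0.5, 0), c(0.65, 0.35, 0))
  manual <- P_nb2
  for (x in 1:3) {
    cv <- sum((P_obs[, x] - mean(P_obs[, x])) *
              (P_nb2[, x] - mean(P_nb2[, x]))) / (K - 1)
    vr <- sum((P_obs[, x] - mean(P_obs[, x]))^2) / (K - 1)
    C <- cv / max(vr, 1e-10)
    manual[, x] <- P_nb2[, x] + C * delta[, x]
  }
  manual <- manual / rowSums(manual)
  expect_equal(covariability_adjust(P_obs, P_nb2, delta), manual)
})

test_that("adjusted triples are projected back to the simplex", {
  P_obs <- rbind(c(0.1, 0.9, 0), c(0.9, 0.1, 0), c(0.5, 0.5, 0))
  P_nb <- P_obs
  delta <- rbind(c(-0.5, 0.5, 0), c(0.5, -0.5, 0), c(0, 0, 0))
  out <- covariability_adjust(P_obs, P_nb, delta)
  expect_true(all(out >= 0 & out <= 1))
  expect_equal(rowSums(out), rep(1, 3))
})

test_that("one assimilation cycle only touches observed nodes and their neighbours", {
  set.seed(403)
  net <- build_er(60, 3)
  config <- inference_config(K = 20, D = 4)
  ens <- init_ensemble(net, config)
  v <- 7L
  obs <- ensir:::new_observation_set(v, 3, "I")
  after <- ensir:::assimilate_day(ens$prob, ens$beta, net, obs, 0L, config)
  changed <- which(apply(abs(after - ens$prob) > 1e-14, 1, any))
  expect_true(all(changed %in% c(v, net$adj[[v]])))
  expect_true(v %in% changed)
})

test_that("inference without observations is the mean ensemble forecast", {
  net <- build_er(40, 3, seed = 404)
  config <- inference_config(K = 15, D = 4)
  empty <- ensir:::new_observation_set(integer(0), integer(0), character(0))

  set.seed(405)
  expect_message(est <- run_inference(net, empty, T = 5, config), "forecast")

  set.seed(405)
  ens <- init_ensemble(net, config)
  ref <- matrix(0, 40, 6)
  for (k in 1:15) {
    states <- integrate_master(ens$prob[, , k], net, ens$beta[, k], 4, 5)
    ref <- ref + vapply(states, function(s) s[, 2], numeric(40))
  }
  expect_equal(est$mean_pI, ref / 15, tolerance = 1e-12)
})

test_that("an observed infection raises risk locally, decaying with distance", {
  net <- path_network(9)
  obs <- ensir:::new_observation_set(5L, 3L, "I")
  set.seed(406)
  est <- run_inference(net, obs, T = 3, inference_config(K = 200, D = 4))
  expect_equal(which.max(est$final), 5)
  by_dist <- vapply(0:3, function(d)
    mean(est$final[c(5 - d, 5 + d)]), numeric(1))
  expect_true(all(diff(by_dist) < 0))
})

test_that("risk estimates are valid probabilities and runs are reproducible", {
  set.seed(407)
  net <- build_er(80, 3)
  tr <- simulate_sir(net, 0.25, 4, seeds = 1:4, T = 5)
  obs <- random_testing(tr, 0.05, 0.3, 0.05)
  config <- inference_config(K = 25, D = 4)
  set.seed(408)
  e1 <- suppressWarnings(run_inference(net, obs, 5, config))
  set.seed(408)
  e2 <- suppressWarnings(run_inference(net, obs, 5, config))
  expect_identical(e1, e2)
  expect_true(all(e1$mean_pI >= 0 & e1$mean_pI <= 1))
  expect_error(run_inference(net, obs, 2, config), "beyond")

  rk <- risk_ranking(e1)
  expect_equal(rk$score, sort(e1$final, decreasing = TRUE))
  expect_equal(rk$rank, 1:80)
})
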