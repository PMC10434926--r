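# Ensemble Bayesian inference of unobserved infections.
#
# The inference object is an ensemble of K probability states, each paired
# with its own per-node transmission-rate vector drawn from a uniform prior
# (deliberately NOT the bimodal truth used by the simulator). Three
# procedures run on each day t up to the last observation day:
#
#   1. backward temporal propagation -- for every observation (v, t_o >= t, O)
#      each member updates node v's day-t marginals by Bayes' rule,
#      posterior(X) ~ prior(X) * P(O at t_o | X at t), with the likelihood
#      built from a provisional (adjustment-free) forecast of that member;
#   2. cross-ensemble covariability adjustment -- the observed node's update
#      delta is regressed onto each neighbour j via
#      C = cov_K(P(X_v), P(X_j)) / var_K(P(X_v)) and applied member-wise,
#      a Kalman-regression update computed across the ensemble;
#   3. model integration -- one master-equation step to day t+1.
#
# The headline output is the ensemble-mean per-node P(I) on the final day.

#' Inference configuration
#'
#' @param K ensemble size (>= 2; the covariance update needs spread).
#' @param beta_lo,beta_hi uniform prior range for per-node transmission
#'   rates. The default `[0.10, 0.30]` brackets the bimodal truth (means
#'   0.18/0.22) without matching it.
#' @param p0 upper bound of the small uniform initial infection probability
#'   assigned to every node in every member.
#' @param D mean infectious period used by the inference model (days).
#' @param var_floor lower bound on the ensemble variance in the regression
#'   denominator, guarding against ensemble collapse.
#' @return a list of class `inference_config`.
#' @export
inference_config <- function(K = 100, beta_lo = 0.10, beta_hi = 0.30,
                             p0 = 0.01, D = 4, var_floor = 1e-10) {
  if (K < 2) stop("K must be at least 2: the ensemble covariance needs spread")
  if (beta_lo > beta_hi) stop("beta_lo must not exceed beta_hi")
  if (p0 < 0 || p0 > 1) stop("p0 must lie in [0, 1]")
  if (var_floor <= 0) stop("var_floor must be positive")
  structure(list(K = as.integer(K), beta_lo = beta_lo, beta_hi = beta_hi,
                 p0 = p0, D = D, var_floor = var_floor),
            class = "inference_config")
}

#' Initialize an inference ensemble
#'
#' Each member gets independent per-node initial infection probabilities
#' `pI ~ Uniform(0, p0)` (with `pS = 1 - pI`, `pR = 0`) and independent
#' per-node transmission rates `beta ~ Uniform(beta_lo, beta_hi)`.
#'
#' @param network an `epi_network`.
#' @param config an [inference_config()].
#' @return a `sir_ensemble`: list with `prob` (n x 3 x K array), `beta`
#'   (n x K matrix) and `config`.
#' @export
init_ensemble <- function(network, config = inference_config()) {
  n <- network$n; K <- config$K
  prob <- array(0, dim = c(n, 3, K))
  for (k in seq_len(K)) {
    pI <- stats::runif(n, 0, config$p0)
    prob[, 1, k] <- 1 - pI
    prob[, 2, k] <- pI
  }
  beta <- matrix(stats::runif(n * K, config$beta_lo, config$beta_hi), n, K)
  structure(list(prob = prob, beta = beta, config = config),
            class = "sir_ensemble")
}

#' @export
print.sir_ensemble <- function(x, ...) {
  cat(sprintf("sir_ensemble: %d members, %d nodes, beta prior U(%.2f, %.2f)\n",
              dim(x$prob)[3], dim(x$prob)[1],
              x$config$beta_lo, x$config$beta_hi))
  invisible(x)
}

#' Backward Bayes update of state marginals given a later observation
#'
#' `posterior(X) ~ prior(X) * likelihood(X)`, where `likelihood(X)` is the
#' probability of the observed state at the observation day given state X at
#' the current day (a column of [conditional_likelihood()]). If the
#' observation has zero probability under the prior, the posterior falls
#' back to the indicator of the state with the largest likelihood.
#'
#' @param prior length-3 probability vector, or a K x 3 matrix (one row per
#'   ensemble member).
#' @param likelihood length-3 vector `L[X, O]`, or a K x 3 matrix.
#' @return list with `posterior` and `delta = posterior - prior`, shaped
#'   like `prior`.
#' @export
bayes_backward_update <- function(prior, likelihood) {
  vec <- !is.matrix(prior)
  P <- if (vec) matrix(prior, 1) else prior
  L <- if (is.matrix(likelihood)) likelihood
       else matrix(likelihood, nrow(P), 3, byrow = TRUE)
  w <- P * L
  tot <- rowSums(w)
  dead <- tot <= 0
  if (any(dead)) {
    warning("observation impossible under prior; using least-impossible state")
    for (i in which(dead)) {
      w[i, ] <- 0
      w[i, which.max(L[i, ])] <- 1
      tot[i] <- 1
    }
  }
  post <- w / tot
  if (vec) post <- drop(post)
  list(posterior = post, delta = post - prior)
}

#' Cross-ensemble covariability adjustment of a neighbour
#'
#' Regresses the observed node's per-member update onto a neighbour:
#' for each state X, `C = cov_K(P(X_obs), P(X_nb)) / max(var_K(P(X_obs)),
#' var_floor)` computed across members from the PRIOR (pre-update) values,
#' then `P(X_nb) <- P(X_nb) + C * delta(X_obs)` member-wise. Adjusted triples
#' are projected back to the simplex (clip to [0, 1], renormalize; a row
#' losing all mass reverts to its input).
#'
#' @param P_obs K x 3 matrix of the observed node's prior marginals.
#' @param P_nb K x 3 matrix of the neighbour's marginals.
#' @param delta K x 3 matrix of the observed node's Bayes updates.
#' @param var_floor variance floor.
#' @return adjusted K x 3 matrix for the neighbour.
#' @export
covariability_adjust <- function(P_obs, P_nb, delta, var_floor = 1e-10) {
  out <- P_nb
  for (x in 1:3) {
    C <- stats::cov(P_obs[, x], P_nb[, x]) /
      max(stats::var(P_obs[, x]), var_floor)
    out[, x] <- P_nb[, x] + C * delta[, x]
  }
  project_simplex_rows(out, fallback = P_nb)
}

project_simplex_rows <- function(m, fallback) {
  m[m < 0] <- 0
  m[m > 1] <- 1
  tot <- rowSums(m)
  dead <- tot <= 0
  if (any(dead)) {
    m[dead, ] <- fallback[dead, , drop = FALSE]
    tot[dead] <- rowSums(m[dead, , drop = FALSE])
  }
  m / tot
}

# One assimilation pass at day t: backward updates + covariability
# adjustments for all observations with day >= t, in ascending (day, node)
# order. `prob` is the n x 3 x K ensemble array; returns the updated array.
# Changes only observed nodes and their direct neighbours.
assimilate_day <- function(prob, beta, network, obs, t, config) {
  todo <- obs[obs$day >= t, , drop = FALSE]
  if (nrow(todo) == 0) return(prob)
  n <- dim(prob)[1]; K <- dim(prob)[3]
  t_last <- max(todo$day)
  m_max <- t_last - t

  # provisional adjustment-free forecast per member: pI for days t..t_last
  pIf <- array(0, dim = c(n, m_max + 1, K))
  for (k in seq_len(K)) {
    Pk <- prob[, , k]
    pIf[, 1, k] <- Pk[, 2]
    if (m_max > 0) for (d in seq_len(m_max)) {
      Pk <- forward_step(Pk, network, beta[, k], config$D)
      pIf[, d + 1, k] <- Pk[, 2]
    }
  }

  state_code <- match(todo$state, .STATES)
  for (o in seq_len(nrow(todo))) {
    v <- todo$node[o]; t_o <- todo$day[o]; m <- t_o - t
    bv <- beta[v, ]
    if (m == 0) {
      H <- matrix(0, K, 0)
    } else {
      nb <- network$adj[[v]]
      Q <- matrix(1, m, K)
      for (j in nb) {
        Pj <- pIf[j, seq_len(m), , drop = TRUE]
        if (m == 1) Pj <- matrix(Pj, 1, K)
        Q <- Q * (1 - Pj * matrix(bv, m, K, byrow = TRUE))
      }
      H <- t(1 - Q)
    }
    lik <- likelihood_column(H, config$D, state_code[o])
    prior_v <- t(prob[v, , ])
    upd <- bayes_backward_update(prior_v, lik)
    prob[v, , ] <- t(upd$posterior)
    for (j in network$adj[[v]]) {
      prob[j, , ] <- t(covariability_adjust(
        prior_v, t(prob[j, , ]), upd$delta, config$var_floor))
    }
  }
  prob
}

#' Run the ensemble inference
#'
#' @param network an `epi_network`.
#' @param obs an `observation_set` (may be empty, giving a pure ensemble
#'   forecast).
#' @param T final day of interest; must be >= the last observation day.
#' @param config an [inference_config()].
#' @return a `risk_estimate`: list with `mean_pI` (n x (T+1) matrix of
#'   ensemble-mean infection probabilities, days 0..T as columns), `final`
#'   (day-T vector, the headline ranking score) and `T`.
#' @export
run_inference <- function(network, obs, T, config = inference_config()) {
  if (nrow(obs) > 0 && max(obs$day) > T)
    stop("observations must not lie beyond day T")
  ens <- init_ensemble(network, config)
  prob <- ens$prob; beta <- ens$beta
  n <- network$n; K <- config$K
  t_last <- if (nrow(obs) > 0) max(obs$day) else 0L
  if (nrow(obs) == 0) message("empty observation set: pure ensemble forecast")

  mean_pI <- matrix(0, n, T + 1)
  mean_pI[, 1] <- rowMeans(prob[, 2, , drop = FALSE])
  t <- 0L
  while (t < t_last) {
    prob <- assimilate_day(prob, beta, network, obs, t, config)
    for (k in seq_len(K))
      prob[, , k] <- forward_step(prob[, , k], network, beta[, k], config$D)
    t <- t + 1L
    mean_pI[, t + 1] <- rowMeans(prob[, 2, , drop = FALSE])
  }
  while (t < T) {
    for (k in seq_len(K))
      prob[, , k] <- forward_step(prob[, , k], network, beta[, k], config$D)
    t <- t + 1L
    mean_pI[, t + 1] <- rowMeans(prob[, 2, , drop = FALSE])
  }
  structure(list(mean_pI = mean_pI, final = mean_pI[, T + 1], T = T,
                 K = K),
            class = "risk_estimate")
}

#' @export
print.risk_estimate <- function(x, ...) {
  cat(sprintf(
    "risk_estimate: %d nodes, day %d, mean final P(I) = %.3f, top node %d\n",
    length(x$final), x$T, mean(x$final), which.max(x$final)))
  invisible(x)
}

#' Export a risk estimate as a ranking table
#' @param est a `risk_estimate`.
#' @return data.frame `node`, `score`, `rank` (1 = highest risk).
#' @export
risk_ranking <- function(est) {
  ord <- order(est$final, decreasing = TRUE)
  data.frame(node = ord, score = est$final[ord],
             rank = seq_along(ord))
}
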