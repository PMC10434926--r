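# Per-node SIR master equations under the neighbour-independence closure.
#
# A probability state is an n x 3 matrix (columns S, I, R) of per-node
# marginals. One forward step applies the exact one-day discretization
#
#   h_i      = 1 - prod_{j in adj(i)} (1 - beta_i * pI_j)
#   pS_i'    = pS_i * (1 - h_i)
#   pI_i'    = pI_i * (1 - 1/D) + pS_i * h_i
#   pR_i'    = pR_i + pI_i / D
#
# matching the daily Bernoulli simulator. beta_i sits inside node i's own
# product: transmission-rate heterogeneity lives on the susceptible side.
# The update conserves the per-node simplex analytically; tiny negative
# values from floating error are clipped and renormalized.

#' Construct a probability state
#'
#' @param n number of nodes.
#' @param pI optional per-node initial infection probability (default all 0);
#'   `pS` is set to `1 - pI`, `pR` to 0.
#' @return an n x 3 numeric matrix with columns `S`, `I`, `R`.
#' @export
probability_state <- function(n, pI = 0) {
  pI <- rep_len(pI, n)
  if (any(pI < 0 | pI > 1)) stop("pI must lie in [0, 1]")
  m <- cbind(S = 1 - pI, I = pI, R = 0)
  m
}

#' Per-node daily infection hazard
#'
#' `h_i = 1 - prod over neighbours j of (1 - beta_i * pI_j)`, the probability
#' that susceptible node i is infected today given independent neighbour
#' marginals.
#'
#' @param prob probability state (n x 3 matrix) or a per-node `pI` vector.
#' @param network an `epi_network`.
#' @param beta per-node transmission rates.
#' @return numeric vector of hazards in `[0, 1]` (0 for isolated nodes).
#' @export
infection_hazard <- function(prob, network, beta) {
  pI <- if (is.matrix(prob)) prob[, 2] else prob
  n <- network$n
  if (length(beta) == 1) beta <- rep(beta, n)
  if (length(pI) != n || length(beta) != n) stop("length mismatch with network")
  if (length(network$src) == 0) return(numeric(n))
  v <- log1p(-pmin(beta[network$dst] * pI[network$src], 1))
  s <- numeric(n)
  agg <- rowsum(v, network$dst)
  s[as.integer(rownames(agg))] <- agg
  -expm1(s)
}

#' One forward step of the master equations
#'
#' @param prob n x 3 probability state.
#' @param network an `epi_network`.
#' @param beta per-node transmission rates.
#' @param D mean infectious period (days); `Inf` disables recovery.
#' @return the probability state one day later.
#' @export
forward_step <- function(prob, network, beta, D) {
  if (!is.matrix(prob) || ncol(prob) != 3 || nrow(prob) != network$n)
    stop("prob must be an n x 3 matrix matching the network")
  h <- infection_hazard(prob, network, beta)
  r <- if (is.infinite(D)) 0 else 1 / D
  out <- cbind(S = prob[, 1] * (1 - h),
               I = prob[, 2] * (1 - r) + prob[, 1] * h,
               R = prob[, 3] + prob[, 2] * r)
  clean_simplex(out)
}

clean_simplex <- function(m) {
  if (any(m < -1e-12)) warning("probability state needed clipping beyond 1e-12")
  m[m < 0] <- 0
  m / rowSums(m)
}

#' Integrate the master equations over several days
#'
#' @inheritParams forward_step
#' @param n_days number of daily steps (>= 0).
#' @return list of `n_days + 1` probability states (input first).
#' @export
integrate_master <- function(prob, network, beta, D, n_days) {
  if (n_days < 0) stop("n_days must be >= 0")
  out <- vector("list", n_days + 1)
  out[[1]] <- prob
  for (d in seq_len(n_days))
    out[[d + 1]] <- forward_step(out[[d]], network, beta, D)
  out
}

#' Conditional state-transition likelihood over a day range
#'
#' For one node, the 3x3 matrix `L[X, O] = P(state O at t_to | state X at
#' t_from)`, given the node's daily infection hazards on days t_from ..
#' t_to - 1. Each day contributes the transition matrix
#' `[[1-h, h, 0], [0, 1-1/D, 1/D], [0, 0, 1]]`; `L` is their ordered product.
#' An empty hazard vector gives the identity (t_to = t_from).
#'
#' @param hazards numeric vector of daily hazards (possibly length 0).
#' @param D mean infectious period.
#' @return 3x3 row-stochastic matrix with dimnames S/I/R.
#' @export
conditional_likelihood <- function(hazards, D) {
  if (any(is.na(hazards))) stop("hazard series has missing days")
  r <- if (is.infinite(D)) 0 else 1 / D
  L <- diag(3)
  for (h in hazards) {
    M <- rbind(c(1 - h, h, 0),
               c(0, 1 - r, r),
               c(0, 0, 1))
    L <- L %*% M
  }
  dimnames(L) <- list(.STATES, .STATES)
  L
}

# Vectorized likelihood column across ensemble members.
# H: K x m matrix of daily hazards (m = number of days); returns K x 3 matrix
# lik[, X] = P(O at t+m | X at t) for the observed state O.
# Closed form of the ordered product in conditional_likelihood():
#   S->S: prod(1-h); S->I: sum_d prod_{<d}(1-h) h_d (1-r)^(m-d);
#   I->I: (1-r)^m; R->R: 1.
likelihood_column <- function(H, D, obs_state) {
  K <- nrow(H); m <- ncol(H)
  r <- if (is.infinite(D)) 0 else 1 / D
  if (m == 0) {
    lik <- matrix(0, K, 3)
    lik[, obs_state] <- 1
    return(lik)
  }
  q <- 1 - H
  cq <- matrix(1, K, m)   # cq[, d] = prod_{d' < d} q[, d']
  if (m > 1) for (d in 2:m) cq[, d] <- cq[, d - 1] * q[, d - 1]
  SS <- cq[, m] * q[, m]
  decay <- (1 - r) ^ ((m - 1):0)
  SI <- as.vector((cq * H) %*% decay)
  II <- (1 - r) ^ m
  lik <- switch(obs_state,
    `1` = cbind(SS, 0, 0),
    `2` = cbind(SI, II, 0),
    `3` = cbind(1 - SS - SI, 1 - II, 1))
  unname(lik)
}
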