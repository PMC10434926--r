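# Competing risk-ranking baselines: Degree, Contact, and a modified
# dynamic message-passing (DMP) algorithm.
#
# DMP propagates per-directed-edge messages
#   theta(k->i): probability no infection signal has passed k -> i yet
#   phi(k->i):   probability k is infectious and has not yet transmitted to i
# with receiver-side transmission rates (beta of the susceptible endpoint),
# exactly mirroring the simulator's convention. On trees with exact initial
# conditions the resulting marginals coincide with the stochastic SIR law.
# Observations enter by clamping observed nodes' marginals at the
# observation day and rescaling their outgoing phi messages proportionally
# -- an explicit reconstruction used here only as a comparison method.

#' Degree ranking
#'
#' Nodes with more contacts are assumed more likely to be infected.
#'
#' @param network an `epi_network`.
#' @return numeric score vector (the node degrees).
#' @export
degree_scores <- function(network) {
  as.numeric(degrees(network))
}

#' Contact-with-observed-infections ranking
#'
#' Scores each node by its number of distinct neighbours ever observed in
#' state I.
#'
#' @param network an `epi_network`.
#' @param obs an `observation_set`.
#' @return numeric score vector.
#' @export
contact_scores <- function(network, obs) {
  inf_nodes <- unique(obs$node[obs$state == "I"])
  vapply(network$adj, function(nb) sum(nb %in% inf_nodes), numeric(1))
}

#' Modified dynamic message-passing ranking
#'
#' Runs discrete-time SIR DMP forward from day 0 with every node assigned a
#' small initial infection probability `p0`. On each day with observations,
#' observed nodes' marginals are overwritten by the observed indicator and
#' their outgoing `phi` messages rescaled by the same factor as the
#' infectious marginal. The score is the marginal P(I) on day `T`.
#'
#' @param network an `epi_network`.
#' @param obs an `observation_set`.
#' @param T final day.
#' @param mode `"fixed"`: all transmission rates equal
#'   `(beta_lo + beta_hi)/2` (DMP1); `"uniform"`: per-node rates drawn from
#'   `Uniform(beta_lo, beta_hi)` (DMP2).
#' @param beta_lo,beta_hi prior transmission-rate range.
#' @param D mean infectious period.
#' @param p0 initial infection probability per node.
#' @param beta optional explicit per-node rates (overrides `mode`; used to
#'   hand the true rates to DMP).
#' @return numeric score vector (final-day marginal P(I)).
#' @export
dmp_scores <- function(network, obs, T, mode = c("fixed", "uniform"),
                       beta_lo = 0.10, beta_hi = 0.30, D = 4, p0 = 0.01,
                       beta = NULL) {
  mode <- match.arg(mode)
  n <- network$n
  if (is.null(beta)) {
    beta <- if (mode == "fixed") rep((beta_lo + beta_hi) / 2, n)
            else stats::runif(n, beta_lo, beta_hi)
  }
  marg <- dmp_forward(network, beta, D, pI0 = rep(p0, n), T = T, obs = obs)
  marg$pI[, T + 1]
}

# Discrete-time SIR DMP with optional observation clamping.
# pI0: per-node initial infection probability (pS0 = 1 - pI0, pR0 = 0).
# Returns list of n x (T+1) matrices pS, pI, pR; with trace_messages = TRUE
# also `theta`, the per-directed-edge message at each day (ne x (T+1)).
dmp_forward <- function(network, beta, D, pI0, T, obs = NULL,
                        trace_messages = FALSE) {
  n <- network$n
  src <- network$src; dst <- network$dst
  ne <- length(src)
  r <- if (is.infinite(D)) 0 else 1 / D
  pS0 <- 1 - pI0

  pS <- matrix(0, n, T + 1); pI <- pS; pR <- pS
  pS[, 1] <- pS0; pI[, 1] <- pI0
  s_cur <- pS0; i_cur <- pI0; r_cur <- rep(0, n)

  clamp <- function(t) {
    if (is.null(obs)) return()
    rows <- which(obs$day == t)
    for (o in rows) {
      v <- obs$node[o]
      tgt <- c(S = 0, I = 0, R = 0)
      tgt[obs$state[o]] <- 1
      old_i <- i_cur[v]
      s_cur[v] <<- tgt[1]; i_cur[v] <<- tgt[2]; r_cur[v] <<- tgt[3]
      # rescale outgoing phi proportionally to the infectious overwrite
      out_e <- which(src == v)
      ratio <- if (old_i > 1e-12) tgt[2] / old_i else tgt[2]
      phi[out_e] <<- pmin(1, phi[out_e] * ratio)
    }
  }

  if (ne == 0) {
    phi <- numeric(0)
    clamp(0)
    pS[, 1] <- s_cur; pI[, 1] <- i_cur; pR[, 1] <- r_cur
    for (t in seq_len(T)) {
      i_new <- i_cur * (1 - r); r_cur <- r_cur + i_cur * r; i_cur <- i_new
      clamp(t)
      pS[, t + 1] <- s_cur; pI[, t + 1] <- i_cur; pR[, t + 1] <- r_cur
    }
    return(list(pS = pS, pI = pI, pR = pR))
  }

  # rev_e[e]: index of the reversed directed edge
  eid <- paste(src, dst); rid <- paste(dst, src)
  rev_e <- match(rid, eid)
  b_e <- beta[dst]                      # receiver-side rate on each edge
  theta <- rep(1, ne)
  phi <- pI0[src]
  ps_cav <- pS0[src]                    # cavity P_S(k -> i) at current day
  prod_in <- function(th) {
    # per-node product of incoming theta, then cavity ratio per edge
    lg <- log(pmax(th, 1e-300))
    s <- numeric(n)
    agg <- rowsum(lg, dst)
    s[as.integer(rownames(agg))] <- agg
    list(node = exp(s), s = s, lg = lg)
  }
  clamp(0)
  pS[, 1] <- s_cur; pI[, 1] <- i_cur; pR[, 1] <- r_cur
  theta_trace <- if (trace_messages) matrix(0, ne, T + 1) else NULL
  if (trace_messages) theta_trace[, 1] <- theta

  pin <- prod_in(theta)
  for (t in seq_len(T)) {
    theta_new <- pmax(theta - b_e * phi, 0)
    pin_new <- prod_in(theta_new)
    # cavity product over l in adj(src) \ dst: node product / theta(dst->src)
    ps_cav_new <- pS0[src] * exp(pin_new$s[src] - pin_new$lg[rev_e])
    phi <- (1 - b_e) * (1 - r) * phi + pmax(ps_cav - ps_cav_new, 0)
    phi <- pmin(pmax(phi, 0), 1)
    theta <- theta_new
    ps_cav <- ps_cav_new

    # marginals: recursive susceptible update keeps clamps persistent
    ratio_node <- exp(pin_new$s - pin$s)
    s_new <- s_cur * pmin(ratio_node, 1)
    r_new <- r_cur + r * i_cur
    i_new <- pmin(pmax(1 - s_new - r_new, 0), 1)
    s_cur <- s_new; i_cur <- i_new; r_cur <- pmin(r_new, 1)
    pin <- pin_new
    clamp(t)
    if (trace_messages) theta_trace[, t + 1] <- theta
    pS[, t + 1] <- s_cur; pI[, t + 1] <- i_cur; pR[, t + 1] <- r_cur
  }
  list(pS = pS, pI = pI, pR = pR, theta = theta_trace)
}
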