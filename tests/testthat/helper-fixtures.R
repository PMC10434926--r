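# Shared fixtures and independent oracles. Everything here is built in code;
# the oracles deliberately avoid the package's own computational paths.

path_network <- function(n) {
  ensir::epi_network(n, cbind(seq_len(n - 1), 2:n))
}

star_network <- function(leaves) {
  ensir::epi_network(leaves + 1, cbind(1, 1 + seq_len(leaves)))
}

# Hand-made trajectory from an n x (T+1) matrix of "S"/"I"/"R" labels.
make_trajectory <- function(labels) {
  codes <- matrix(match(labels, c("S", "I", "R")), nrow(labels))
  structure(list(states = codes, T = ncol(labels) - 1,
                 seeds = which(codes[, 1] == 2L)),
            class = "sir_trajectory")
}

check_network_invariants <- function(net) {
  e <- net$edges
  expect_true(all(e[, 1] < e[, 2]))                   # no self-loops
  expect_equal(anyDuplicated(e), 0)                   # no duplicate edges
  for (i in seq_len(net$n)) for (j in net$adj[[i]])
    expect_true(i %in% net$adj[[j]])                  # symmetry
  expect_true(all(unlist(net$adj) >= 1) || net$n == 0)
  expect_lte(max(c(0, unlist(net$adj))), net$n)
}

# Exact joint-state dynamic programming oracle for the daily SIR process.
# Enumerates the full joint distribution over state vectors (3^n states),
# so it is exact for any graph; only feasible for n <= ~6. Returns an
# n x 3 x (T+1) array of exact marginals P(node state on day t).
exact_sir_marginals <- function(net, beta, D, seeds, T) {
  n <- net$n
  r <- if (is.infinite(D)) 0 else 1 / D
  nstates <- 3^n
  decode <- function(s) as.integer((s %/% 3^(0:(n - 1))) %% 3 + 1)  # 1=S,2=I,3=R
  code_mat <- vapply(0:(nstates - 1), decode, integer(n))  # n x nstates
  prob <- numeric(nstates)
  init <- rep(1L, n); init[seeds] <- 2L
  prob[sum((init - 1) * 3^(0:(n - 1))) + 1] <- 1

  marg <- array(0, dim = c(n, 3, T + 1))
  record <- function(day) {
    for (s in which(prob > 0)) {
      st <- code_mat[, s]
      for (i in 1:n) marg[i, st[i], day + 1] <<- marg[i, st[i], day + 1] + prob[s]
    }
  }
  record(0)
  for (day in seq_len(T)) {
    newp <- numeric(nstates)
    for (s in which(prob > 0)) {
      st <- code_mat[, s]
      # per-node next-state distributions
      opts <- vector("list", n)
      for (i in 1:n) {
        if (st[i] == 1L) {
          m <- sum(st[net$adj[[i]]] == 2L)
          p_inf <- 1 - (1 - beta[i])^m
          opts[[i]] <- c(`1` = 1 - p_inf, `2` = p_inf)
        } else if (st[i] == 2L) {
          opts[[i]] <- c(`2` = 1 - r, `3` = r)
        } else opts[[i]] <- c(`3` = 1)
      }
      combos <- expand.grid(lapply(opts, function(o) as.integer(names(o))))
      pr <- apply(expand.grid(lapply(opts, unname)), 1, prod)
      for (ci in seq_len(nrow(combos))) {
        if (pr[ci] == 0) next
        ns <- sum((as.integer(combos[ci, ]) - 1) * 3^(0:(n - 1))) + 1
        newp[ns] <- newp[ns] + prob[s] * pr[ci]
      }
    }
    prob <- newp
    record(day)
  }
  marg
}

# Brute-force path-sum oracle for the single-node conditional likelihood:
# enumerate all state paths through the daily 3-state chain.
chain_likelihood_oracle <- function(hazards, D) {
  r <- if (is.infinite(D)) 0 else 1 / D
  day_matrix <- function(h) rbind(c(1 - h, h, 0), c(0, 1 - r, r), c(0, 0, 1))
  m <- length(hazards)
  L <- matrix(0, 3, 3)
  paths <- expand.grid(rep(list(1:3), m + 1))
  for (p in seq_len(nrow(paths))) {
    pa <- as.integer(paths[p, ])
    w <- 1
    for (d in seq_len(m)) w <- w * day_matrix(hazards[d])[pa[d], pa[d + 1]]
    L[pa[1], pa[m + 1]] <- L[pa[1], pa[m + 1]] + w
  }
  L
}

# Concordant-pair AUC oracle (exhaustive over positive/negative pairs).
pair_count_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
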