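# Observation models: sparse, time-stamped, perfect tests.
#
# An observation set is the data D = {(node, day, state)} consumed by every
# inference method. Tests are perfect: an observation always reports the
# trajectory's true state at (node, day). Testing starts on day 1 so the
# seeding event itself is never observed directly.

new_observation_set <- function(node, day, state) {
  df <- data.frame(node = as.integer(node), day = as.integer(day),
                   state = as.character(state), stringsAsFactors = FALSE)
  df <- df[!duplicated(df[, c("node", "day")]), , drop = FALSE]
  df <- df[order(df$day, df$node), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("observation_set", "data.frame")
  df
}

#' State-dependent random daily testing
#'
#' Each node is tested independently on each day 1..T with a probability
#' that depends on its true state that day (`q_I` is typically largest:
#' infected people are more likely to present for testing). Every test
#' yields a perfect observation.
#'
#' @param trajectory a `sir_trajectory`.
#' @param q_S,q_I,q_R daily testing probabilities per state.
#' @return an `observation_set` (data.frame: `node`, `day`, `state`).
#' @export
random_testing <- function(trajectory, q_S, q_I, q_R) {
  for (q in c(q_S, q_I, q_R))
    if (q < 0 || q > 1) stop("testing probabilities must lie in [0, 1]")
  st <- trajectory$states
  n <- nrow(st); T <- trajectory$T
  qs <- c(q_S, q_I, q_R)
  days <- rep(1:T, each = n)
  state_codes <- as.vector(st[, 2:(T + 1), drop = FALSE])
  tested <- stats::runif(n * T) < qs[state_codes]
  new_observation_set(rep(seq_len(n), T)[tested], days[tested],
                      .STATES[state_codes[tested]])
}

#' Contact-tracing observation model
#'
#' Base state-dependent daily testing as in [random_testing()]; in addition,
#' whenever a node is observed in state I on day t, all its network
#' neighbours are tested (with certainty) on day t+1. Positive traced tests
#' trigger further tracing the following day.
#'
#' @inheritParams random_testing
#' @param network the `epi_network` the outbreak ran on.
#' @return an `observation_set`.
#' @export
contact_tracing <- function(trajectory, network, q_S, q_I, q_R) {
  for (q in c(q_S, q_I, q_R))
    if (q < 0 || q > 1) stop("testing probabilities must lie in [0, 1]")
  st <- trajectory$states
  n <- nrow(st); T <- trajectory$T
  if (T < 1) stop("trajectory must span at least one day")
  qs <- c(q_S, q_I, q_R)
  node_l <- list(); day_l <- list(); state_l <- list()
  to_trace <- integer(0)   # neighbours due for a traced test today
  for (t in 1:T) {
    codes <- st[, t + 1]
    tested <- which(stats::runif(n) < qs[codes])
    tested <- sort(unique(c(tested, to_trace)))
    if (length(tested) > 0) {
      node_l[[t]] <- tested
      day_l[[t]] <- rep(t, length(tested))
      state_l[[t]] <- .STATES[codes[tested]]
      pos <- tested[codes[tested] == 2L]
      to_trace <- if (length(pos) > 0)
        unique(unlist(network$adj[pos])) else integer(0)
    } else to_trace <- integer(0)
  }
  new_observation_set(unlist(node_l), unlist(day_l), unlist(state_l))
}

#' Fraction of distinct nodes with at least one observation
#'
#' @param obs an `observation_set`.
#' @param n_nodes network size.
#' @return fraction in `[0, 1]`.
#' @export
observed_fraction <- function(obs, n_nodes) {
  if (nrow(obs) == 0) return(0)
  length(unique(obs$node)) / n_nodes
}

#' Default daily testing probabilities
#'
#' Calibrated presets for the default ER outbreak, producing observed
#' fractions near 16%, 30% and 50% of nodes -- the operating range of the
#' study conditions. `q_I > q_S = q_R` throughout: infected individuals are
#' more likely to be tested.
#'
#' @param level one of `"low"`, `"medium"`, `"high"`.
#' @return named list `q_S`, `q_I`, `q_R`.
#' @export
default_testing_rates <- function(level = c("low", "medium", "high")) {
  level <- match.arg(level)
  switch(level,
    low    = list(q_S = 0.018, q_I = 0.090, q_R = 0.018),
    medium = list(q_S = 0.038, q_I = 0.190, q_R = 0.038),
    high   = list(q_S = 0.075, q_I = 0.300, q_R = 0.075))
}

#' Write / read an observation set as CSV
#' @param obs an `observation_set`.
#' @param path file path.
#' @export
write_observations <- function(obs, path) {
  utils::write.csv(as.data.frame(obs), path, row.names = FALSE)
}

#' @rdname write_observations
#' @return `read_observations()` returns an `observation_set`.
#' @export
read_observations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("node", "day", "state") %in% names(df)))
    stop("observation CSV needs columns node, day, state")
  if (!all(df$state %in% .STATES)) stop("state column must be S, I or R")
  new_observation_set(df$node, df$day, df$state)
}
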