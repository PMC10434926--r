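# Reproducible experiment driver: generate -> simulate -> observe -> infer
# (all methods) -> evaluate, with replicate management and a runtime
# scaling benchmark.
#
# Seeding discipline: the master seed draws one child seed per replicate;
# within a replicate, the network/outbreak/observation stage and each
# inference method get fixed-offset sub-seeds, so adding or removing
# methods never perturbs the simulated data.

#' Default ER benchmark experiment configuration
#'
#' The packaged study conditions: ER network of 1,000 nodes with mean degree
#' 2.6, bimodal transmission rates, growth-phase outbreak, state-dependent
#' testing at the low observation level (~16% of nodes observed), 100-member
#' ensemble with a uniform `[0.10, 0.30]` transmission-rate prior.
#'
#' @param observation_level `"low"`, `"medium"` or `"high"` testing preset.
#' @param replicates number of independent replicates.
#' @return a list of class `experiment_config`.
#' @export
default_experiment_config <- function(observation_level = "low",
                                      replicates = 10) {
  ob <- default_outbreak_config()
  structure(list(
    network = list(family = "er", n = ob$n, mean_degree = ob$mean_degree),
    outbreak = list(beta = ob$beta, D = ob$D, seed_frac = ob$seed_frac,
                    T = ob$T),
    observation = c(list(model = "random"),
                    default_testing_rates(observation_level)),
    inference = list(K = 100, beta_lo = 0.10, beta_hi = 0.30, p0 = 0.01,
                     var_floor = 1e-10),
    methods = c("ens", "dmp1", "dmp2", "degree", "contact"),
    replicates = as.integer(replicates)),
    class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' @param path YAML file; fields follow [default_experiment_config()].
#'   Missing fields fall back to the defaults.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  user <- yaml::read_yaml(path)
  config <- unclass(default_experiment_config())
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(config[[nm]]))
      config[[nm]] <- utils::modifyList(config[[nm]], user[[nm]])
    else config[[nm]] <- user[[nm]]
  }
  config$methods <- unlist(config$methods)
  structure(config, class = "experiment_config")
}

build_network_from_spec <- function(spec) {
  switch(spec$family,
    er = build_er(spec$n, spec$mean_degree),
    tree = build_complete_tree(spec$branching, spec$depth),
    powerlaw = build_powerlaw_config(spec$n, spec$gamma,
                                     if (is.null(spec$k_min)) 1 else spec$k_min),
    regular = build_random_regular(spec$n, spec$k),
    edgelist = read_edge_list(spec$path),
    stop("unknown network family: ", spec$family))
}

run_one_method <- function(method, network, obs, T, inf_spec) {
  switch(method,
    ens = run_inference(network, obs, T,
            inference_config(K = inf_spec$K, beta_lo = inf_spec$beta_lo,
                             beta_hi = inf_spec$beta_hi, p0 = inf_spec$p0,
                             D = inf_spec$D,
                             var_floor = inf_spec$var_floor))$final,
    dmp1 = dmp_scores(network, obs, T, mode = "fixed",
                      beta_lo = inf_spec$beta_lo, beta_hi = inf_spec$beta_hi,
                      D = inf_spec$D, p0 = inf_spec$p0),
    dmp2 = dmp_scores(network, obs, T, mode = "uniform",
                      beta_lo = inf_spec$beta_lo, beta_hi = inf_spec$beta_hi,
                      D = inf_spec$D, p0 = inf_spec$p0),
    degree = degree_scores(network),
    contact = contact_scores(network, obs),
    stop("unknown method: ", method))
}

#' Run a full experiment
#'
#' Per replicate: generate the network, sample transmission rates and seeds,
#' simulate the outbreak, draw observations, run every requested method, and
#' evaluate each ranking (tie-aware AUC against final-day infectious status
#' over all nodes).
#'
#' @param config an `experiment_config`.
#' @param seed master integer seed; the run is fully reproducible from
#'   `(config, seed)`.
#' @param out_dir optional directory: per-replicate metrics, the resolved
#'   config (YAML) and the seed are written there.
#' @return data.frame with one row per (replicate, method): columns
#'   `replicate`, `method`, `attack_rate`, `observed_fraction`, `auc`.
#' @export
run_experiment <- function(config, seed = 1L, out_dir = NULL) {
  inf_spec <- config$inference
  inf_spec$D <- config$outbreak$D
  rep_seeds <- with_seed(seed,
    sample.int(2^31 - 1000, config$replicates))
  rows <- vector("list", config$replicates)
  for (r in seq_len(config$replicates)) {
    srep <- rep_seeds[r]
    dat <- with_seed(srep, {
      network <- build_network_from_spec(config$network)
      beta <- sample_beta_spec(config$outbreak$beta, network$n)
      n_seeds <- max(1L, round(config$outbreak$seed_frac * network$n))
      sds <- sample.int(network$n, n_seeds)
      traj <- simulate_sir(network, beta, config$outbreak$D, sds,
                           config$outbreak$T)
      ospec <- config$observation
      obs <- if (identical(ospec$model, "contact"))
        contact_tracing(traj, network, ospec$q_S, ospec$q_I, ospec$q_R)
      else random_testing(traj, ospec$q_S, ospec$q_I, ospec$q_R)
      list(network = network, traj = traj, obs = obs)
    })
    truth_ok <- length(unique(
      dat$traj$states[, dat$traj$T + 1] == 2L)) == 2
    res <- lapply(seq_along(config$methods), function(mi) {
      method <- config$methods[mi]
      scores <- with_seed(srep + mi, run_one_method(
        method, dat$network, dat$obs, dat$traj$T, inf_spec))
      auc <- if (truth_ok)
        evaluate_ranking(scores, dat$traj, dat$obs)$auc else NA_real_
      data.frame(replicate = r, method = method,
                 attack_rate = attack_rate(dat$traj),
                 observed_fraction = observed_fraction(dat$obs,
                                                       dat$network$n),
                 auc = auc)
    })
    rows[[r]] <- do.call(rbind, res)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    yaml::write_yaml(c(unclass(config), list(seed = seed)),
                     file.path(out_dir, "config.yaml"))
  }
  out
}

#' Runtime scaling benchmark
#'
#' Times the full per-replicate pipeline (simulate, observe, infer with the
#' ensemble method) at several levels of one swept quantity and fits the
#' log-log slope of runtime against level. Slopes are reported, never
#' asserted: they depend on hardware and implementation constants.
#'
#' @param base_config an `experiment_config` (replicates ignored).
#' @param sweep one of `"n_nodes"`, `"n_obs"`, `"mean_degree"`, `"K"`.
#' @param levels numeric vector of at least 3 sweep levels.
#' @param repeats timed repetitions per level.
#' @param seed integer seed.
#' @return list with `table` (data.frame `level`, `repeat`, `seconds`) and
#'   `slope` (fitted log-log exponent).
#' @export
scaling_benchmark <- function(base_config, sweep, levels, repeats = 3,
                              seed = 1L) {
  sweep <- match.arg(sweep, c("n_nodes", "n_obs", "mean_degree", "K"))
  if (length(levels) < 3) stop("need at least 3 sweep levels")
  rows <- list()
  for (lv in levels) for (rp in seq_len(repeats)) {
    config <- base_config
    if (sweep == "n_nodes") config$network$n <- as.integer(lv)
    if (sweep == "mean_degree") config$network$mean_degree <- lv
    if (sweep == "K") config$inference$K <- as.integer(lv)
    el <- with_seed(seed + rp + round(1000 * lv), {
      network <- build_network_from_spec(config$network)
      beta <- sample_beta_spec(config$outbreak$beta, network$n)
      sds <- sample.int(network$n,
                        max(1L, round(config$outbreak$seed_frac * network$n)))
      traj <- simulate_sir(network, beta, config$outbreak$D, sds,
                           config$outbreak$T)
      ospec <- config$observation
      obs <- random_testing(traj, ospec$q_S, ospec$q_I, ospec$q_R)
      if (sweep == "n_obs") {
        keep <- seq_len(min(nrow(obs), as.integer(lv)))
        obs <- obs[sample.int(nrow(obs))[keep], , drop = FALSE]
        class(obs) <- c("observation_set", "data.frame")
      }
      inf_spec <- config$inference; inf_spec$D <- config$outbreak$D
      system.time(run_one_method("ens", network, obs, traj$T, inf_spec))[[3]]
    })
    rows[[length(rows) + 1]] <- data.frame(level = lv, rep = rp,
                                           seconds = el)
  }
  tab <- do.call(rbind, rows)
  fit <- stats::lm(log(seconds) ~ log(level),
                   data = stats::aggregate(seconds ~ level, tab, stats::median))
  list(table = tab, slope = unname(stats::coef(fit)[2]))
}
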