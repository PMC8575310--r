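#' Experiment configuration
#'
#' Builds and validates a sweep-experiment configuration.  `experiment` is
#' one of `"smallworld"` (sweep over the rewiring probability q),
#' `"scalefree"` (sweep over the power-law exponent gamma) or `"star"`
#' (sweep over the number of leaves n).
#'
#' @param experiment experiment kind.
#' @param nodes number of nodes N (ignored for `"star"`).
#' @param avg_degree lattice degree k (small-world) or minimum degree k_min
#'   (scale-free).
#' @param sweep vector of sweep values: q in \[0,1\], gamma > 2, or n >= 1.
#' @param n_graphs networks generated per sweep point.
#' @param ensemble_size runs per network.
#' @param seed master seed.
#' @param output optional output path used by [write_sweep()] callers.
#' @return a validated list of class `experiment_config`.
#' @export
experiment_config <- function(experiment, nodes, avg_degree, sweep,
                              n_graphs, ensemble_size, seed, output = NULL) {
  experiment <- match.arg(experiment, c("smallworld", "scalefree", "star"))
  bad <- switch(experiment,
    smallworld = any(sweep < 0 | sweep > 1),
    scalefree = any(sweep <= 2),
    star = any(sweep < 1)
  )
  if (bad)
    stop("sweep values out of domain for experiment '", experiment, "'",
         call. = FALSE)
  if (length(sweep) < 1) stop("empty sweep", call. = FALSE)
  if (n_graphs < 1 || ensemble_size < 1)
    stop("n_graphs and ensemble_size must be >= 1", call. = FALSE)
  structure(
    list(experiment = experiment, nodes = as.integer(nodes),
         avg_degree = as.integer(avg_degree), sweep = as.numeric(sweep),
         n_graphs = as.integer(n_graphs),
         ensemble_size = as.integer(ensemble_size),
         seed = as.integer(seed), output = output),
    class = "experiment_config"
  )
}

#' Read / write experiment configurations (YAML)
#'
#' @param path YAML file path.
#' @return [load_config()] returns a validated `experiment_config`;
#'   [save_config()] writes one and returns it invisibly.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  need <- c("experiment", "nodes", "avg_degree", "sweep", "n_graphs",
            "ensemble_size", "seed")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("config is missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  experiment_config(raw$experiment, raw$nodes, raw$avg_degree, raw$sweep,
                    raw$n_graphs, raw$ensemble_size, raw$seed, raw$output)
}

#' @rdname load_config
#' @param config an `experiment_config`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(config)
}

#' Small-world sweep over the rewiring probability
#'
#' For each q in the sweep, generates `n_graphs` Watts-Strogatz graphs
#' (N nodes, lattice degree k), runs `ensemble_size` fixation trials on
#' each with a uniformly placed single mutant, and pools successes.  At
#' q = 0 the graph is regular, every death rate is 1, and the estimate
#' should sit at the Moran value 1/N; increasing q increases the degree
#' fluctuation and with it the fixation probability.
#'
#' @param config an `experiment_config` with `experiment = "smallworld"`.
#' @return a `data.frame` (one row per q): `q`, `p_hat`, `se` (pooled
#'   binomial), `sd_graphs` (SD of per-graph estimates), `delta_mean`
#'   (mean empirical degree fluctuation), `moran` (1/N), `runs`,
#'   `successes`.
#' @export
run_smallworld_sweep <- function(config) {
  stopifnot(inherits(config, "experiment_config"),
            config$experiment == "smallworld")
  sweep_core(config, function(q) {
    function() make_small_world(config$nodes, config$avg_degree, q)
  }, param_name = "q")
}

#' Scale-free sweep over the power-law exponent
#'
#' For each gamma, generates `n_graphs` configuration-model graphs with
#' degrees sampled from `p(k) ~ k^-gamma`, `k >= k_min` (`avg_degree` plays
#' the role of k_min), and pools fixation trials as in
#' [run_smallworld_sweep()].  Estimates decrease toward 1/N as gamma grows
#' and the degree distribution narrows.
#'
#' @param config an `experiment_config` with `experiment = "scalefree"`.
#' @return a `data.frame` as in [run_smallworld_sweep()], with column
#'   `gamma` instead of `q` plus `avg_degree_mean` (realized mean degree).
#' @export
run_scalefree_sweep <- function(config) {
  stopifnot(inherits(config, "experiment_config"),
            config$experiment == "scalefree")
  sweep_core(config, function(gamma) {
    function() make_scale_free(config$nodes, gamma, k_min = config$avg_degree)
  }, param_name = "gamma")
}

sweep_core <- function(config, make_generator, param_name) {
  rows <- vector("list", length(config$sweep))
  set.seed(config$seed)
  for (s in seq_along(config$sweep)) {
    val <- config$sweep[s]
    gen <- make_generator(val)
    deltas <- kbars <- numeric(0)
    gen_rec <- function() {
      g <- gen()
      st <- degree_stats(g)
      deltas <<- c(deltas, st$fluctuation)
      kbars <<- c(kbars, st$mean)
      g
    }
    est <- estimate_fixation_probability(
      gen_rec, ensemble_size = config$ensemble_size,
      n_graphs = config$n_graphs, seed = NULL
    )
    rows[[s]] <- data.frame(
      param = val,
      p_hat = est$probability,
      se = est$std_error,
      sd_graphs = est$sd_across_graphs,
      delta_mean = mean(deltas),
      avg_degree_mean = mean(kbars),
      moran = 1 / config$nodes,
      runs = est$runs,
      successes = est$successes
    )
  }
  out <- do.call(rbind, rows)
  names(out)[1] <- param_name
  out
}

#' Star-graph experiment: exact solution vs simulation
#'
#' For each n in `n_min..n_max`, solves the star master equation exactly and
#' estimates the same two quantities by Monte Carlo: the fixation
#' probability of a single mutant starting in the core (`pi_0^1`) and on a
#' leaf (`pi_1^0`), alongside the well-mixed Moran baseline `1/(n+1)`.
#'
#' @param n_min,n_max range of leaf counts.
#' @param ensemble_size simulation runs per starting condition and n.
#' @param seed master seed.
#' @return a `data.frame` with columns `n`, `pi_core`, `pi_leaf` (exact),
#'   `sim_core`, `sim_leaf`, `se_core`, `se_leaf`, `moran`, `ratio_check`
#'   (exact `pi_leaf / pi_core` minus [star_fixation_ratio()]).
#' @export
run_star_experiment <- function(n_min, n_max, ensemble_size, seed) {
  stopifnot(n_min >= 1, n_min <= n_max, ensemble_size >= 1)
  set.seed(seed)
  rows <- lapply(n_min:n_max, function(n) {
    sol <- solve_star(n)
    g <- make_star(n)
    core <- estimate_fixation_probability(g, ensemble_size,
                                          initial_mutant = 1L)
    leaf <- estimate_fixation_probability(g, ensemble_size,
                                          initial_mutant = 2L)
    data.frame(
      n = n,
      pi_core = sol$pi1[1], pi_leaf = sol$pi0[2],
      sim_core = core$probability, sim_leaf = leaf$probability,
      se_core = core$std_error, se_leaf = leaf$std_error,
      moran = 1 / (n + 1),
      ratio_check = sol$pi0[2] / sol$pi1[1] - star_fixation_ratio(n)
    )
  })
  do.call(rbind, rows)
}

#' Run the experiment named by a configuration
#'
#' @param config an `experiment_config`.
#' @return the sweep `data.frame` of the matching `run_*` function; for
#'   `"star"`, [run_star_experiment()] over the sweep's range of n.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  switch(config$experiment,
    smallworld = run_smallworld_sweep(config),
    scalefree = run_scalefree_sweep(config),
    star = run_star_experiment(min(config$sweep), max(config$sweep),
                               config$ensemble_size, config$seed)
  )
}

#' Write a sweep result as annotated CSV
#'
#' Plain CSV with a `#` comment line recording the seed and package
#' version, then a header row.  Deterministic for a fixed config and seed.
#'
#' @param result a sweep `data.frame`.
#' @param path output file.
#' @param seed seed to record in the comment line.
#' @return `invisible(NULL)`.
#' @export
write_sweep <- function(result, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# degreedrift %s  seed=%s",
                     as.character(utils::packageVersion("degreedrift")),
                     format(seed)), con)
  utils::write.table(result, con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(NULL)
}
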