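#' Mutant death rate at a node
#'
#' Under the degree-coupled model a mutant occupying node `i` dies at rate
#' `k_i / <k>`; wild types die at rate 1 everywhere.  Averaged over all
#' nodes the mutant death rate is exactly 1 (since `sum(k_i) = N <k>`), so
#' drift is neutral only on average.
#'
#' @param graph an igraph graph.
#' @param node node id (1..N); if missing, rates for all nodes are returned.
#' @return numeric rate(s) `degree(node) / avg_degree`.
#' @export
mutant_death_rate <- function(graph, node) {
  stopifnot(igraph::is_igraph(graph))
  deg <- igraph::degree(graph)
  kbar <- mean(deg)
  if (missing(node)) return(deg / kbar)
  if (!is.numeric(node) || any(node < 1) || any(node > length(deg)))
    stop("unknown node id", call. = FALSE)
  deg[node] / kbar
}

#' Create a population state
#'
#' A state is an integer vector of length N with 1 marking mutants (B) and 0
#' wild types (A), plus a `mutant_count` attribute.
#'
#' @param graph an igraph graph.
#' @param mutants node ids initially occupied by mutants.
#' @return an integer 0/1 vector of class `population_state`.
#' @export
population_state <- function(graph, mutants) {
  N <- igraph::vcount(graph)
  if (any(mutants < 1) || any(mutants > N))
    stop("mutant node ids out of range", call. = FALSE)
  s <- integer(N)
  s[mutants] <- 1L
  structure(s, mutant_count = sum(s), class = "population_state")
}

#' Offspring-placement (death-selection) probabilities
#'
#' Given a reproducing node, each of its neighbours is selected to die with
#' probability proportional to its death rate: 1 for a wild type, `k_j/<k>`
#' for a mutant at node j, renormalized over the neighbourhood.  The
#' reproducer itself is never a candidate.
#'
#' @param graph an igraph graph.
#' @param state a 0/1 occupancy vector (see [population_state()]).
#' @param reproducer node id of the reproducing individual.
#' @return a named numeric vector of probabilities over the reproducer's
#'   neighbours; sums to 1.
#' @export
death_selection_probs <- function(graph, state, reproducer) {
  N <- igraph::vcount(graph)
  if (reproducer < 1 || reproducer > N)
    stop("unknown reproducer node", call. = FALSE)
  nb <- as.integer(igraph::neighbors(graph, reproducer))
  if (length(nb) == 0L)
    stop("node ", reproducer, " is isolated; dynamics requires a connected graph",
         call. = FALSE)
  dm <- mutant_death_rate(graph)
  w <- ifelse(state[nb] == 1L, dm[nb], 1)
  p <- w / sum(w)
  names(p) <- nb
  p
}

#' One birth-death update step
#'
#' A reproducer is drawn uniformly over all N nodes (all birth rates are 1);
#' one of its neighbours is drawn to die according to
#' [death_selection_probs()]; the victim takes the reproducer's label.
#'
#' @param graph an igraph graph.
#' @param state current occupancy vector; must not be absorbing (all 0 or
#'   all 1).
#' @param reproducer optional: force the reproducing node (used in tests);
#'   default draws uniformly.
#' @return the updated `population_state`.
#' @export
bd_step <- function(graph, state, reproducer = NULL) {
  N <- igraph::vcount(graph)
  m <- sum(state == 1L)
  if (m == 0L || m == N)
    stop("state is absorbing; no further BD steps are defined", call. = FALSE)
  if (is.null(reproducer)) reproducer <- sample.int(N, 1L)
  p <- death_selection_probs(graph, state, reproducer)
  nb <- as.integer(names(p))
  victim <- nb[sample.int(length(nb), 1L, prob = p)]
  state[victim] <- state[reproducer]
  structure(as.integer(state), mutant_count = sum(state == 1L),
            class = "population_state")
}

#' Run the BD process to fixation or loss
#'
#' Iterates BD steps (in compiled code) until the mutant lineage either
#' occupies every node (fixation) or vanishes (loss).
#'
#' @param graph a connected igraph graph with at least 2 nodes.
#' @param initial_mutant node id of the single starting mutant, or
#'   `"uniform"` to draw it uniformly.
#' @param max_steps safety cap on BD events (default 1e9).
#' @param mutant_death optional custom per-node mutant death rates
#'   (default `k_i / <k>`).
#' @return a list with `fixed` (logical) and `steps` (number of BD events).
#' @export
run_to_fixation <- function(graph, initial_mutant = "uniform",
                            max_steps = 1e9, mutant_death = NULL) {
  N <- igraph::vcount(graph)
  if (N < 2) stop("graph must have at least 2 nodes", call. = FALSE)
  if (!igraph::is_connected(graph))
    stop("graph must be connected", call. = FALSE)
  start <- if (identical(initial_mutant, "uniform")) {
    sample.int(N, 1L)
  } else {
    stopifnot(is.numeric(initial_mutant), length(initial_mutant) == 1L,
              initial_mutant >= 1, initial_mutant <= N)
    as.integer(initial_mutant)
  }
  csr <- graph_csr(graph)
  dm <- if (is.null(mutant_death)) mutant_death_rate(graph) else mutant_death
  res <- bd_ensemble_cpp(csr$ptr, csr$adj, dm, start - 1L, max_steps)
  list(fixed = res$fixed[1L] == 1L, steps = res$steps[1L])
}

#' Monte-Carlo fixation-probability estimate
#'
#' Repeats [run_to_fixation()] `ensemble_size` times per graph, each run
#' starting from a single mutant placed uniformly at random (or at a fixed
#' node), and pools successes over `n_graphs` independently generated
#' graphs.  All randomness flows from one `set.seed(seed)` stream, so a
#' seed reproduces the estimate exactly, step counts included.
#'
#' @param graph an igraph graph, or a zero-argument generator function
#'   returning a fresh graph (drawn `n_graphs` times inside the seeded
#'   stream).
#' @param ensemble_size runs per graph.
#' @param n_graphs number of graphs (must be 1 when `graph` is a fixed
#'   graph).
#' @param seed integer master seed; `NULL` continues the current stream.
#' @param initial_mutant `"uniform"` or a node id.
#' @param max_steps safety cap per run.
#' @return an object of class `fixation_estimate`: list with `successes`,
#'   `runs`, `probability`, `std_error` (binomial), `sd_across_graphs`
#'   (SD of per-graph estimates, `NA` for one graph), `per_graph`
#'   (data.frame), `mean_steps` and `seed`.
#' @export
estimate_fixation_probability <- function(graph, ensemble_size,
                                          n_graphs = 1L, seed = NULL,
                                          initial_mutant = "uniform",
                                          max_steps = 1e9) {
  stopifnot(ensemble_size >= 1, n_graphs >= 1)
  if (!is.function(graph) && n_graphs != 1L)
    stop("n_graphs > 1 requires a generator function", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  per <- vector("list", n_graphs)
  total_steps <- 0
  for (gidx in seq_len(n_graphs)) {
    G <- if (is.function(graph)) graph() else graph
    if (!igraph::is_connected(G))
      stop("graph ", gidx, " is not connected", call. = FALSE)
    N <- igraph::vcount(G)
    csr <- graph_csr(G)
    dm <- mutant_death_rate(G)
    starts <- if (identical(initial_mutant, "uniform")) {
      sample.int(N, ensemble_size, replace = TRUE)
    } else {
      rep(as.integer(initial_mutant), ensemble_size)
    }
    res <- bd_ensemble_cpp(csr$ptr, csr$adj, dm, starts - 1L, max_steps)
    per[[gidx]] <- data.frame(
      graph = gidx, n_nodes = N, runs = ensemble_size,
      successes = sum(res$fixed), p_hat = mean(res$fixed)
    )
    total_steps <- total_steps + sum(res$steps)
  }
  per <- do.call(rbind, per)
  successes <- sum(per$successes)
  runs <- sum(per$runs)
  p <- successes / runs
  structure(
    list(
      successes = successes, runs = runs, probability = p,
      std_error = sqrt(p * (1 - p) / runs),
      sd_across_graphs = if (n_graphs > 1L) stats::sd(per$p_hat) else NA_real_,
      per_graph = per,
      mean_steps = total_steps / runs,
      seed = if (is.null(seed)) NA_integer_ else seed
    ),
    class = "fixation_estimate"
  )
}

#' @export
print.fixation_estimate <- function(x, ...) {
  cat(sprintf("Fixation estimate: %d / %d runs  p = %.5g (SE %.3g)\n",
              x$successes, x$runs, x$probability, x$std_error))
  if (!is.na(x$sd_across_graphs))
    cat(sprintf("  across %d graphs, SD of per-graph estimates %.3g\n",
                nrow(x$per_graph), x$sd_across_graphs))
  cat(sprintf("  mean steps to absorption %.1f; seed %s\n",
              x$mean_steps, format(x$seed)))
  invisible(x)
}

# CSR adjacency (0-based) for the compiled simulator
graph_csr <- function(graph) {
  adjl <- igraph::as_adj_list(graph)
  lens <- lengths(adjl)
  list(
    ptr = c(0L, cumsum(as.integer(lens))),
    adj = as.integer(unlist(adjl, use.names = FALSE)) - 1L
  )
}
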