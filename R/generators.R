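#' Star graph
#'
#' A central core (node 1) connected to `n_leaves` leaves.  The core has
#' degree n, every leaf degree 1, and the average degree is `2n/(n+1)`.
#'
#' @param n_leaves number of leaves (>= 1).
#' @return an igraph graph with `n_leaves + 1` nodes; node 1 is the core.
#' @export
make_star <- function(n_leaves) {
  if (!is.numeric(n_leaves) || length(n_leaves) != 1L || n_leaves < 1)
    stop("n_leaves must be a positive integer", call. = FALSE)
  igraph::make_star(n_leaves + 1L, mode = "undirected", center = 1L)
}

#' Complete graph
#'
#' @param n_nodes number of nodes (>= 2).
#' @return K_N as an igraph graph; every degree is N-1 and the degree
#'   fluctuation is 0.
#' @export
make_complete <- function(n_nodes) {
  if (!is.numeric(n_nodes) || length(n_nodes) != 1L || n_nodes < 2)
    stop("n_nodes must be >= 2", call. = FALSE)
  igraph::make_full_graph(n_nodes, directed = FALSE)
}

#' Ring lattice
#'
#' Circular lattice on `n_nodes` nodes where node i is linked to its
#' `even_degree / 2` nearest neighbours on each side.  Regular, so the
#' degree fluctuation is exactly 0.
#'
#' @param n_nodes number of nodes.
#' @param even_degree degree of every node; must be even and `< n_nodes`.
#' @return an igraph graph with `n_nodes * even_degree / 2` edges.
#' @export
make_ring_lattice <- function(n_nodes, even_degree) {
  if (even_degree %% 2 != 0 || even_degree < 2)
    stop("even_degree must be a positive even integer", call. = FALSE)
  if (even_degree >= n_nodes)
    stop("even_degree must be smaller than n_nodes", call. = FALSE)
  n <- as.integer(n_nodes)
  half <- as.integer(even_degree / 2)
  i <- rep(seq_len(n), each = half)
  j <- ((i + rep(seq_len(half), times = n) - 1L) %% n) + 1L
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::add_edges(g, rbind(i, j))
}

#' Small-world graph by Watts-Strogatz rewiring
#'
#' Starts from [make_ring_lattice()] and visits each lattice edge once in a
#' fixed order; with probability `rewiring_prob` the far endpoint is detached
#' and reattached to a node chosen uniformly at random, rejecting self-loops
#' and duplicate edges.  `q = 0` returns the lattice unchanged; `q = 1`
#' yields a random graph.  The edge count `N k / 2` is conserved exactly.
#' If the rewired graph is disconnected the construction is retried from the
#' continuing random stream, up to `max_tries` times.
#'
#' @param n_nodes,avg_degree lattice parameters (see [make_ring_lattice()]).
#' @param rewiring_prob rewiring probability q in \[0, 1\].
#' @param seed optional integer seed (`set.seed`); `NULL` uses the current
#'   RNG stream.
#' @param max_tries connectivity retries before giving up.
#' @return a connected simple igraph graph.
#' @export
make_small_world <- function(n_nodes, avg_degree, rewiring_prob,
                             seed = NULL, max_tries = 100L) {
  if (!is.numeric(rewiring_prob) || rewiring_prob < 0 || rewiring_prob > 1)
    stop("rewiring_prob must lie in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  lattice <- make_ring_lattice(n_nodes, avg_degree)
  if (rewiring_prob == 0) return(lattice)
  n <- igraph::vcount(lattice)
  el0 <- igraph::as_edgelist(lattice, names = FALSE)
  for (try in seq_len(max_tries)) {
    el <- el0
    # adjacency hash for O(1) duplicate checks
    key <- function(x, y) pmin(x, y) * (n + 1) + pmax(x, y)
    present <- new.env(hash = TRUE, size = 2L * nrow(el))
    for (e in seq_len(nrow(el)))
      assign(as.character(key(el[e, 1], el[e, 2])), TRUE, envir = present)
    for (e in seq_len(nrow(el))) {
      if (runif(1) >= rewiring_prob) next
      from <- el[e, 1]; old <- el[e, 2]
      # rejection-sample a new far endpoint
      for (att in 1:100) {
        cand <- sample.int(n, 1L)
        if (cand == from) next
        if (exists(as.character(key(from, cand)), envir = present)) next
        rm(list = as.character(key(from, old)), envir = present)
        assign(as.character(key(from, cand)), TRUE, envir = present)
        el[e, 2] <- cand
        break
      }
    }
    g <- igraph::make_empty_graph(n, directed = FALSE)
    g <- igraph::add_edges(g, t(el))
    if (igraph::is_connected(g)) return(g)
  }
  stop("small-world rewiring produced a disconnected graph in every one of ",
       max_tries, " attempts", call. = FALSE)
}

#' Scale-free graph from a sampled power-law degree sequence
#'
#' Draws node degrees i.i.d. from the discrete power law
#' `p(k) proportional to k^-gamma` on `k_min .. n_nodes - 1`, forces the
#' degree sum even by resampling one node, and realizes the sequence as a
#' simple *connected* graph with [igraph::sample_degseq()]
#' (Viger-Latapy method).  Non-graphical or unrealizable draws are retried
#' up to `max_tries` times.
#'
#' @param n_nodes number of nodes.
#' @param gamma power-law exponent (> 2).
#' @param k_min minimum degree (default 2, which keeps connected
#'   realizations reachable).
#' @param seed optional integer seed.
#' @param max_tries bounded retries for unrealizable degree sequences.
#' @return a connected simple igraph graph whose degree distribution follows
#'   the sampled power law.
#' @export
make_scale_free <- function(n_nodes, gamma, k_min = 2L, seed = NULL,
                            max_tries = 100L) {
  if (!is.numeric(gamma) || gamma <= 2)
    stop("gamma must exceed 2", call. = FALSE)
  if (k_min < 1) stop("k_min must be >= 1", call. = FALSE)
  if (n_nodes <= k_min + 1)
    stop("n_nodes too small for k_min = ", k_min, call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ks <- k_min:(n_nodes - 1L)
  pk <- ks^(-gamma)
  pk <- pk / sum(pk)
  last_err <- NULL
  for (try in seq_len(max_tries)) {
    degs <- sample(ks, n_nodes, replace = TRUE, prob = pk)
    if (sum(degs) %% 2 == 1) {
      degs[1L] <- sample(ks, 1L, prob = pk)
      if (sum(degs) %% 2 == 1) degs[1L] <- degs[1L] + 1L
    }
    g <- tryCatch(
      igraph::sample_degseq(degs, method = "vl"),
      error = function(e) e
    )
    if (igraph::is_igraph(g)) return(g)
    last_err <- conditionMessage(g)
  }
  stop("no realizable power-law degree sequence after ", max_tries,
       " attempts (last error: ", last_err, ")", call. = FALSE)
}

#' The 12-node worked-example graph
#'
#' A deterministic 12-node, 18-edge fixture reproducing the worked example of
#' the degree-coupled death rule: node 11 has the six neighbours
#' \{1, 2, 4, 6, 7, 10\}; nodes 2 and 6 have degree 2 and node 10 degree 5;
#' the average degree is 3.  Nodes 2, 6 and 10 carry the mutants, so with
#' `d_B(i) = k_i / 3` the death rates seen from node 11 are 1, 2/3, 1, 2/3,
#' 1, 5/3 and the offspring-placement probabilities are
#' 1/6, 1/9, 1/6, 1/9, 1/6, 5/18.  Edges not fixed by those constraints are
#' one documented choice.
#'
#' @return a list with components `graph` (igraph, nodes 1..12) and
#'   `mutants` (integer vector `c(2, 6, 10)`).
#' @export
make_fig1_graph <- function() {
  edges <- rbind(
    c(11, 1), c(11, 2), c(11, 4), c(11, 6), c(11, 7), c(11, 10),
    c(2, 3), c(6, 5),
    c(10, 3), c(10, 5), c(10, 8), c(10, 9),
    c(12, 1), c(12, 3), c(12, 4), c(12, 5), c(12, 7), c(12, 8)
  )
  g <- igraph::make_empty_graph(12, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  list(graph = g, mutants = c(2L, 6L, 10L))
}
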