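#' Degree statistics of a graph
#'
#' Computes the empirical degree distribution `p(k) = N_k / N`, the first two
#' degree moments, and the degree fluctuation
#' `Delta = <k^2> / <k>^2 - 1`, the normalized degree variance that drives
#' the fixation-probability deviation in the degree-coupled BD model.
#' `Delta` is 0 exactly iff the graph is regular.
#'
#' @param graph an igraph graph.
#' @return an object of class `degree_stats`: a list with `counts` (named
#'   integer vector, `N_k` by degree k), `p` (named numeric, `N_k / N`),
#'   `mean` (`<k>`), `second_moment` (`<k^2>`), `fluctuation` (`Delta`) and
#'   `n_nodes`.
#' @export
degree_stats <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  deg <- igraph::degree(graph)
  N <- length(deg)
  tab <- table(deg)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  m1 <- sum(deg) / N
  m2 <- sum(deg^2) / N
  structure(
    list(
      counts = counts,
      p = counts / N,
      mean = m1,
      second_moment = m2,
      fluctuation = m2 / m1^2 - 1,
      n_nodes = N
    ),
    class = "degree_stats"
  )
}

#' @export
print.degree_stats <- function(x, ...) {
  cat("Degree statistics over", x$n_nodes, "nodes\n")
  cat("  <k> =", format(x$mean), "  <k^2> =", format(x$second_moment),
      "  Delta =", format(x$fluctuation), "\n")
  cat("  p(k):", paste0(names(x$p), ":", signif(x$p, 4), collapse = "  "),
      "\n")
  invisible(x)
}

#' Theoretical degree fluctuation of a power-law network
#'
#' Closed forms for `Delta = <k^2>/<k>^2 - 1` under a continuous power-law
#' degree distribution with exponent `gamma`:
#' for `gamma > 3`, `Delta = (gamma-2)^2 / ((gamma-1)(gamma-3)) - 1`,
#' independent of scale; for `2 < gamma < 3` the second moment is cut off by
#' the largest degree and
#' `Delta = (gamma-2)^2/((gamma-1)(gamma-3)) *
#'   (1 - ((gamma-1)/(gamma-2) * kmax_over_kbar)^(3-gamma)) - 1`,
#' which grows with the cutoff ratio `k_max / <k>`.
#'
#' @param gamma power-law exponent, `> 2` and `!= 3`.
#' @param kmax_over_kbar ratio `k_max / <k>`; required when `2 < gamma < 3`.
#' @return the fluctuation `Delta` (a non-negative scalar).
#' @examples
#' theoretical_fluctuation(4)            # exactly 1/3
#' theoretical_fluctuation(2.5, kmax_over_kbar = 10)
#' @export
theoretical_fluctuation <- function(gamma, kmax_over_kbar = NULL) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 2)
    stop("gamma must exceed 2", call. = FALSE)
  if (gamma == 3)
    stop("gamma = 3 is singular: the second moment diverges logarithmically",
         call. = FALSE)
  base <- (gamma - 2)^2 / ((gamma - 1) * (gamma - 3))
  if (gamma > 3) return(base - 1)
  if (is.null(kmax_over_kbar) || kmax_over_kbar <= 0)
    stop("for 2 < gamma < 3 a positive kmax_over_kbar is required",
         call. = FALSE)
  base * (1 - ((gamma - 1) / (gamma - 2) * kmax_over_kbar)^(3 - gamma)) - 1
}
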