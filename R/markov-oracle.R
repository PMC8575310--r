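#' Exact fixation probabilities by exhaustive absorbing Markov chain
#'
#' Enumerates all `2^N` mutant/wild-type occupation states, builds the BD
#' transition matrix, and solves the absorbing-chain linear system
#' `(I - Q) x = R` for the probability of reaching the all-mutant state from
#' every single-mutant start.  Deterministic; intended as a brute-force
#' oracle for small graphs.
#'
#' @param graph a connected igraph graph with `N <= cap` nodes.
#' @param mutant_death optional per-node mutant death rates; defaults to the
#'   degree-coupled rule `k_i / <k>`.  (Useful for checking that rates which
#'   never enter any neighbourhood choice -- e.g. the star core's -- leave
#'   the solution unchanged.)
#' @param cap state-space guard: `2^N` states must be enumerable
#'   (default 12).
#' @return a numeric vector of length N: `result[i]` is the fixation
#'   probability starting from a single mutant at node i.
#' @export
exact_fixation_markov <- function(graph, mutant_death = NULL, cap = 12L) {
  stopifnot(igraph::is_igraph(graph))
  N <- igraph::vcount(graph)
  if (N > cap)
    stop("N = ", N, " exceeds the state-space cap of ", cap,
         " (2^N states); raise `cap` deliberately if you mean it",
         call. = FALSE)
  if (!igraph::is_connected(graph))
    stop("graph must be connected", call. = FALSE)
  adjl <- lapply(igraph::as_adj_list(graph), as.integer)
  dm <- if (is.null(mutant_death)) mutant_death_rate(graph) else mutant_death
  stopifnot(length(dm) == N, all(dm > 0))

  bits <- bitwShiftL(1L, 0:(N - 1L))
  masks <- 0:(2^N - 1L)
  popcnt <- rowSums(outer(masks, bits, bitwAnd) > 0L)
  transient <- masks[popcnt > 0L & popcnt < N]
  full <- 2^N - 1L
  id <- integer(2^N)                     # mask -> row index (transient only)
  id[transient + 1L] <- seq_along(transient)

  acc_j <- vector("list", length(transient))
  acc_x <- vector("list", length(transient))
  rhs <- numeric(length(transient))
  for (row in seq_along(transient)) {
    mask <- transient[row]
    s <- bitwAnd(mask, bits) > 0L
    js <- xs <- vector("list", N)
    for (rep_ in seq_len(N)) {
      nb <- adjl[[rep_]]
      w <- ifelse(s[nb], dm[nb], 1)
      w <- w / (N * sum(w))
      new <- if (s[rep_]) bitwOr(mask, bits[nb])
             else bitwAnd(mask, bitwNot(bits[nb]))
      hit_full <- new == full
      if (any(hit_full)) rhs[row] <- rhs[row] + sum(w[hit_full])
      keep <- new != full & new != 0L
      js[[rep_]] <- id[new[keep] + 1L]
      xs[[rep_]] <- w[keep]
    }
    acc_j[[row]] <- unlist(js, use.names = FALSE)
    acc_x[[row]] <- unlist(xs, use.names = FALSE)
  }
  ti <- rep.int(seq_along(transient), lengths(acc_j))
  Q <- Matrix::sparseMatrix(i = ti,
                            j = unlist(acc_j, use.names = FALSE),
                            x = unlist(acc_x, use.names = FALSE),
                            dims = rep(length(transient), 2L))
  x <- Matrix::solve(Matrix::Diagonal(length(transient)) - Q, rhs)
  out <- as.numeric(x[id[bits + 1L]])
  names(out) <- seq_len(N)
  out
}
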