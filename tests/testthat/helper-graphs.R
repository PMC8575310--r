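# Shared fixtures and small helpers for the suite.

# path graph 1-2-...-n
make_path <- function(n) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::add_edges(g, rbind(1:(n - 1), 2:n))
}

# |x - target| within k binomial standard errors at the target
expect_within_se <- function(p_hat, target, runs, k = 3) {
  se <- sqrt(target * (1 - target) / runs)
  expect_lt(abs(p_hat - target), k * se + 1e-12)
}

edge_key_set <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
}
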