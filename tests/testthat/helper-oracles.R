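# Independent spectral oracle used throughout: build the trace-rescaled
# Laplacian explicitly from an igraph Laplacian and take its spectrum via
# svd (valid because the operator is symmetric positive semi-definite).
oracle_entropy <- function(m) {
  g <- igraph::graph_from_adjacency_matrix((m + t(m)) / 2,
                                           mode = "undirected",
                                           weighted = TRUE)
  lap <- as.matrix(igraph::laplacian_matrix(g))
  rho <- lap / sum(diag(lap))
  ev <- svd(rho)$d
  ev <- ev[ev > 1e-14]
  -sum(ev * log2(ev))
}

oracle_jsd <- function(a, b) {
  lap <- function(m) {
    ms <- (m + t(m)) / 2
    l <- diag(rowSums(ms)) - ms
    l / sum(diag(l))
  }
  mix <- (lap(a) + lap(b)) / 2
  ent <- function(rho) {
    ev <- svd(rho)$d
    ev <- ev[ev > 1e-14]
    -sum(ev * log2(ev))
  }
  sqrt(max(ent(mix) - (ent(lap(a)) + ent(lap(b))) / 2, 0))
}
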