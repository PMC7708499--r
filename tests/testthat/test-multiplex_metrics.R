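test_that("multiplex construction is complete, ordered and bounded", {
  net <- synth_net()
  expect_s3_class(net, "multiplex")
  expect_equal(length(net$nodes), 7L)
  expect_equal(names(net$layers), c("stationary_vicinity", "affiliative",
                                    "grooming", "passive_close_proximity"))
  for (m in net$layers) {
    expect_equal(dim(m), c(7L, 7L))
    expect_true(all(diag(m) == 0))
    expect_true(all(m >= 0 & m <= 1))  # weighted mode
  }
  expect_true(isSymmetric(net$layers$stationary_vicinity))
  expect_true(isSymmetric(net$layers$passive_close_proximity))

  # missing dyad rows are an error
  cfg <- synth_config(n_sessions = 5, seed = 42)
  roster <- make_roster(cfg)
  idx <- normalize_weighted(
    compute_indices(simulate_scans(dyad_state_probs(roster, cfg)), roster))
  broken <- idx[-1L, ]
  expect_error(build_multiplex(broken, "GroupA", "weighted"), "expected")
})

test_that("densities count strictly positive off-diagonal entries", {
  z <- matrix(0, 5, 5)
  expect_equal(layer_density(z), 0)
  expect_equal(layer_density(complete_layer(5)), 1)
  # the published multiplex: 168 possible edges, 139 / 166 present
  expect_equal(multiplex_density_from_counts(139, 7, 4), 139 / 168)
  expect_equal(round(multiplex_density_from_counts(139, 7, 4), 2), 0.83)
  expect_equal(round(multiplex_density_from_counts(166, 7, 4), 2), 0.99)
  expect_error(multiplex_density_from_counts(169, 7, 4), "must lie")

  net <- synth_net()
  agg_density <- layer_density(aggregate_layers(net))
  for (m in net$layers) expect_gte(agg_density, layer_density(m))
})

test_that("strength equals the in- plus out-weight sum", {
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- 1
  expect_equal(unname(strength(star, 1)), 3)
  expect_equal(unname(strength(star, 2)), 1)
  expect_equal(unname(strength(matrix(0, 3, 3), 2)), 0)
  set.seed(4)
  m <- random_layer(5)
  expect_equal(strength(m), rowSums(m) + colSums(m))
})

test_that("eigenvector centrality is max-normalized and scale invariant", {
  expect_true(all(eigenvector_centrality(complete_layer(5)) == 1))

  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 1] <- path[2, 3] <- path[3, 2] <- 1
  ec <- eigenvector_centrality(path)
  expect_equal(unname(ec[2]), 1)
  expect_true(ec[1] < 1 && ec[3] < 1)
  # power-iteration oracle (diagonal shift avoids bipartite oscillation)
  v <- rep(1, 3)
  for (i in 1:200) { v <- path %*% v + v; v <- v / max(v) }
  expect_equal(unname(ec), as.numeric(v), tolerance = 1e-8)

  set.seed(7)
  m <- random_layer(6)
  expect_equal(eigenvector_centrality(m), eigenvector_centrality(10 * m))

  # independent implementation cross-check on the symmetrized graph
  g <- igraph::graph_from_adjacency_matrix((m + t(m)) / 2, mode = "undirected",
                                           weighted = TRUE)
  ig <- igraph::eigen_centrality(g)$vector
  expect_equal(unname(eigenvector_centrality(m)), unname(ig),
               tolerance = 1e-6)

  expect_warning(z <- eigenvector_centrality(matrix(0, 3, 3)), "no edges")
  expect_true(all(z == 0))
})

test_that("aggregation is element-wise summation", {
  net <- synth_net()
  expect_equal(aggregate_layers(net, "grooming"), net$layers$grooming)
  expect_equal(aggregate_layers(net),
               net$layers[[1]] + net$layers[[2]] + net$layers[[3]] +
                 net$layers[[4]])
  expect_error(aggregate_layers(net, character(0)), "nonempty")

  a <- matrix(0, 3, 3); a[1, 2] <- 1
  b <- matrix(0, 3, 3); b[2, 3] <- 1
  net2 <- structure(list(nodes = letters[1:3], layers = list(x = a, y = b),
                         layer_names = c("x", "y")), class = "multiplex")
  agg <- aggregate_layers(net2)
  expect_equal(sum(agg > 0), 2L)  # disjoint support unions
})

test_that("versatility reduces to centrality for identical layers", {
  set.seed(12)
  m <- random_layer(6)
  net <- structure(list(nodes = paste0("n", 1:6),
                        layers = list(a = m, b = m, c = m, d = m),
                        layer_names = letters[1:4]), class = "multiplex")
  v <- eigenvector_versatility(net, omega = 1)
  ec <- eigenvector_centrality(m)
  expect_equal(order(-v), order(-ec))
  expect_equal(max(v), 1)
  expect_error(eigenvector_versatility(net, omega = 0), "positive")
})

test_that("versatility matches a brute-force supra-adjacency oracle", {
  # 3-node, 2-layer toy: node 1 strong in layer a only, node 2 mediocre in both
  a <- matrix(0, 3, 3); a[1, 3] <- a[3, 1] <- 1; a[2, 3] <- a[3, 2] <- 0.3
  b <- matrix(0, 3, 3); b[2, 3] <- b[3, 2] <- 0.3
  net <- structure(list(nodes = c("n1", "n2", "n3"),
                        layers = list(a = a, b = b), layer_names = c("a", "b")),
                   class = "multiplex")
  for (omega in c(0.1, 1, 5)) {
    sup <- rbind(cbind(a, omega * diag(3)), cbind(omega * diag(3), b))
    ev <- abs(eigen(sup, symmetric = TRUE)$vectors[, 1])
    oracle <- ev[1:3] + ev[4:6]
    oracle <- oracle / max(oracle)
    expect_equal(unname(eigenvector_versatility(net, omega)), oracle,
                 tolerance = 1e-10)
  }
  # for small omega the single-layer specialist outranks the generalist
  v_small <- eigenvector_versatility(net, 0.05)
  expect_gt(v_small["n1"], v_small["n2"])
  # joint rescaling of weights and omega leaves scores unchanged
  net10 <- net
  net10$layers <- lapply(net$layers, function(m) 10 * m)
  expect_equal(eigenvector_versatility(net10, 10),
               eigenvector_versatility(net, 1), tolerance = 1e-10)
})

test_that("edge overlap is Jaccard on directed edge presence", {
  a <- matrix(0, 3, 3); a[1, 2] <- 0.5; a[2, 3] <- 1
  b <- matrix(0, 3, 3); b[2, 3] <- 0.2; b[3, 1] <- 0.9
  expect_equal(edge_overlap(a, a), 1)
  expect_equal(edge_overlap(a, b), 1 / 3)  # {12,23} vs {23,31}
  c2 <- matrix(0, 3, 3); c2[1, 3] <- 1
  expect_equal(edge_overlap(a, c2), 0)
  expect_warning(z <- edge_overlap(matrix(0, 3, 3), matrix(0, 3, 3)), "empty")
  expect_equal(z, 0)

  # global overlap: enumeration oracle on a random multiplex
  net <- synth_net()
  pres <- lapply(net$layers, function(m) which(m > 0 & row(m) != col(m)))
  inter <- Reduce(intersect, pres)
  uni <- Reduce(union, pres)
  expect_equal(global_edge_overlap(net), length(inter) / length(uni))
  om <- edge_overlap_matrix(net)
  expect_true(isSymmetric(om))
  expect_true(all(diag(om) == 1))
})

test_that("rank report rings are normalized, ranked and ordered", {
  net <- synth_net()
  rep <- rank_report(net, omega = 1)
  expect_equal(colnames(rep$scores),
               c(names(net$layers), "aggregate", "multiplex"))
  expect_true(all(apply(rep$scores, 2, max) == 1))
  expect_true(all(rep$scores >= 0 & rep$scores <= 1))
  # ranks are dense and follow the scores (sorting oracle)
  for (r in colnames(rep$ranks)) {
    s <- rep$scores[, r]
    oracle <- match(-s, sort(unique(-s)))
    expect_equal(unname(rep$ranks[, r]), oracle)
  }
  # identical layers give identical ranks across all rings
  m <- net$layers$grooming
  same <- structure(list(nodes = net$nodes,
                         layers = stats::setNames(list(m, m, m, m),
                                                  names(net$layers)),
                         layer_names = names(net$layers)), class = "multiplex")
  rep2 <- rank_report(same)
  expect_true(all(rep2$ranks == rep2$ranks[, 1]))
})
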