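#!/usr/bin/env Rscript
# Stage 3: multiplex network metrics.
#
# Per group: layer and multiplex densities, interlayer edge overlap, quantum
# Jensen-Shannon distances, structural reducibility (Ward merge sequence and
# relative-entropy curve) and the centrality / versatility rank report.

library(panmux)

roster <- read_biographies("results/data/biographies.csv")
idx <- normalize_weighted(compute_indices(
  read_scans("results/data/scans.csv", roster), roster))
dir.create("results/networks", showWarnings = FALSE)

for (g in unique(roster$group)) {
  net <- build_multiplex(idx, g, weight = "weighted")
  cat(sprintf("\n== %s: %d nodes, multiplex density %.2f ==\n",
              g, length(net$nodes), multiplex_density(net)))
  dens <- vapply(net$layers, layer_density, numeric(1))
  print(round(dens, 2))

  ov <- edge_overlap_matrix(net)
  write.csv(ov, sprintf("results/networks/overlap_%s.csv", g))
  cat(sprintf("global edge overlap: %.2f\n", global_edge_overlap(net)))

  red <- reducibility(net)
  write.csv(red$jsd_matrix, sprintf("results/networks/jsd_%s.csv", g))
  write.csv(red$merge_sequence,
            sprintf("results/networks/merges_%s.csv", g), row.names = FALSE)
  write.csv(data.frame(n_layers = names(red$relative_entropy),
                       relative_entropy = unname(red$relative_entropy)),
            sprintf("results/networks/reducibility_%s.csv", g),
            row.names = FALSE)
  cat(sprintf("reducibility: %d merge steps, optimum at %d layer(s)\n",
              nrow(red$merge_sequence), red$optimal_n_layers))

  rr <- rank_report(net, omega = 1)
  write.csv(data.frame(node = rownames(rr$scores), rr$scores),
            sprintf("results/networks/centrality_scores_%s.csv", g),
            row.names = FALSE)
  write.csv(data.frame(node = rownames(rr$ranks), rr$ranks),
            sprintf("results/networks/centrality_ranks_%s.csv", g),
            row.names = FALSE)
  cat("versatility ranking:",
      paste(names(sort(rr$ranks[, "multiplex"])), collapse = " > "), "\n")

  write_multiplex_graphml(net, "results/networks", prefix = g)
}
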