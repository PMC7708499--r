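#!/usr/bin/env Rscript
# Stage 6: one-shot pipeline run + figures.
#
# Reruns the whole chain through run_pipeline() into a single bundle
# directory (demonstrating the orchestration layer used by external data),
# then renders the report figures: edge-overlap and Jensen-Shannon heatmaps,
# reducibility curves and the per-ring rank table.

library(panmux)

cfg <- pipeline_config(synthetic = list(n_sessions = 60),
                       out_dir = "results/bundle", seed = 20260923)
bundle <- run_pipeline(cfg)
paths <- plot_reports("results/bundle")
cat("bundle written to results/bundle with figures:\n")
cat(paste(" -", paths, collapse = "\n"), "\n")
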