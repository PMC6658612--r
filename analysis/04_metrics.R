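#!/usr/bin/env Rscript
# Stage 4 — node-level graph metrics.
# Eigenvector centrality (global influence) and signed weighted clustering
# coefficient (local influence), always computed on the full graph; the
# 20-node ROI restriction happens downstream by row selection.

suppressPackageStartupMessages(library(oxynet))
outdir <- "results/analysis"
connectomes <- readRDS(file.path(outdir, "connectomes.rds"))
cohort <- readRDS(file.path(outdir, "cohort.rds"))
cfg <- readRDS(file.path(outdir, "config.rds"))

metric_table <- compute_metric_table(connectomes, cohort$subjects,
                                     ec_mode = cfg$ec_mode)
message("Metric table: ", nrow(metric_table), " rows (",
        length(unique(metric_table$subject_id)), " subjects x 2 conditions x ",
        length(unique(metric_table$node_id)), " nodes x 2 metrics)")
for (m in c("ec", "cc")) {
  v <- metric_table$value[metric_table$metric == m]
  message(sprintf("  %s: median %.4g, IQR [%.4g, %.4g]", m, median(v),
                  quantile(v, .25), quantile(v, .75)))
}

write.csv(metric_table, file.path(outdir, "node_metrics.csv"),
          row.names = FALSE)
saveRDS(metric_table, file.path(outdir, "metric_table.rds"))
message("Stage 4 done")
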