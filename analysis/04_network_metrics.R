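#!/usr/bin/env Rscript
# Stage 4: per-node structural metrics of the global sex networks.
#
# Degree, SCI-weighted degree and normalized harmonic centrality per
# condition; the most connected conditions in each sex's network are the
# candidates for the crucial-disease analyses that follow.

suppressMessages({library(mmnet); library(data.table)})

rows <- list()
for (s in c("male", "female")) {
  g <- import_network(file.path("scratch/networks", paste0(s, "_global.csv")),
                      "edgelist_csv")
  deg <- compute_degrees(g)
  hc <- compute_harmonic_centrality(g, normalized = TRUE)
  deg[, harmonic := as.numeric(hc[code])]
  deg[, sex := s]
  rows[[s]] <- deg
  top <- deg[order(-degree)][1:5]
  message(sprintf("%s: top-degree conditions: %s",
                  s, paste(sprintf("%s (%d)", top$code, top$degree), collapse = ", ")))
}
metrics <- rbindlist(rows)
fwrite(metrics, "results/node_metrics.csv")
message(sprintf("wrote results/node_metrics.csv (%d rows)", nrow(metrics)))
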