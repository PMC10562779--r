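#!/usr/bin/env Rscript
# Stage 7: perturbation analyses of the global networks.
#
# Node perturbation: remove each crucial disease (hub, root or burst) one at
# a time and measure the change in the structural metrics, in particular
# average harmonic centrality. Edge perturbation: delete 1%/3%/5% of edges
# at random (three replicates each) and count how many of the top-10
# PageRank hubs survive.

suppressMessages({library(mmnet); library(data.table)})

crucial <- fread("results/crucial_diseases.csv")

node_rows <- list(); edge_rows <- list()
for (s in c("male", "female")) {
  g <- import_network(file.path("scratch/networks", paste0(s, "_global.csv")),
                      "edgelist_csv")
  codes <- intersect(unique(crucial[sex == s, code]), igraph::V(g)$name)
  nr <- node_removal_analysis(g, codes)
  nr[, sex := s]
  node_rows[[s]] <- nr
  worst <- nr[error == FALSE][order(pct_change_avg_harmonic)][1]
  message(sprintf("%s: removing %s cuts average harmonic centrality by %.3f%%",
                  s, worst$removed_code, -worst$pct_change_avg_harmonic))

  er <- edge_removal_analysis(g, seed = derive_seed(1L, 20L + match(s, c("male", "female"))))
  er[, sex := s]
  edge_rows[[s]] <- er
  ov <- er[, .(mean_overlap = mean(overlap_count)), by = level]
  message(sprintf("%s: mean top-10 overlap at 1/3/5%% edge removal: %s",
                  s, paste(sprintf("%.1f", ov$mean_overlap), collapse = " / ")))
}
fwrite(rbindlist(node_rows, fill = TRUE), "results/perturbation_nodes.csv")
fwrite(rbindlist(edge_rows), "results/perturbation_edges.csv")
message("wrote results/perturbation_nodes.csv and results/perturbation_edges.csv")
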