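#!/usr/bin/env Rscript
# Stage 3: construct the multimorbidity networks.
#
# Pair statistics (Salton cosine index, phi, t) are computed within each
# stratum; the SCI cut-off is calibrated per stratum so the SCI network
# keeps exactly as many edges as there are significantly positively
# correlated pairs under the phi screen (t > 2.58, c_ij above the mean).
# Builds the two global sex networks plus the sex x age-band networks.

suppressMessages({library(mmnet); library(data.table); library(igraph)})

cohort <- fread("scratch/cohort/cohort.csv", colClasses = list(character = "patient_id"))
sets <- fread("scratch/cohort/condition_sets.csv", colClasses = list(character = "patient_id"))
universe <- fread("scratch/cohort/universe.csv")
chronic <- universe$code[universe$chronic_flag]

nets <- suppressWarnings(build_stratified_networks(
  cohort, sets, universe$code, chronic_codes = chronic))

dir.create("scratch/networks", recursive = TRUE, showWarnings = FALSE)
rows <- list()
for (label in names(nets)) {
  res <- nets[[label]]
  slug <- gsub(":", "_", label)
  export_network(res$network, file.path("scratch/networks", paste0(slug, ".csv")),
                 "edgelist_csv")
  sm <- summarize_network(res$network)
  rows[[label]] <- data.table(
    stratum = label, N = res$N, q = res$cutoff$q, e = res$cutoff$e,
    sci_cutoff = res$cutoff$sci_cutoff, nodes = sm$n_nodes, edges = sm$n_edges,
    density = sm$density, avg_degree = sm$avg_degree,
    avg_weighted_degree = sm$avg_weighted_degree, avg_harmonic = sm$avg_harmonic)
}
summary_dt <- rbindlist(rows)
fwrite(summary_dt, "results/network_summaries.csv")

for (s in c("male", "female")) {
  g <- nets[[paste0(s, ":global")]]$network
  export_network(g, file.path("scratch/networks", paste0(s, "_global.graphml")), "graphml")
  message(sprintf("%s global network: %d nodes, %d edges, density %.3f",
                  s, vcount(g), ecount(g), summary_dt[stratum == paste0(s, ":global"), density]))
}
message("wrote results/network_summaries.csv and scratch/networks/")
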