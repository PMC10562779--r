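#!/usr/bin/env Rscript
# Stage 5: hub, root, burst and core diseases.
#
# Hubs: top-10 PageRank nodes of each global sex network. Roots: the
# maximum-eigenvector-centrality node of each Louvain community. Bursts:
# conditions whose degree grows by >= 6 between adjacent age-band networks.
# Cores: the three-way intersection, per sex. With planted truth available,
# the script also reports how well communities and hubs were recovered.

suppressMessages({library(mmnet); library(data.table); library(jsonlite)})

truth <- read_json("scratch/synthetic/truth.json", simplifyVector = TRUE)

out_rows <- list()
for (s in c("male", "female")) {
  g <- import_network(file.path("scratch/networks", paste0(s, "_global.csv")),
                      "edgelist_csv")
  bands <- list()
  for (b in age_band_labels()) {
    f <- file.path("scratch/networks", paste0(s, "_", b, ".csv"))
    if (file.exists(f)) bands[[b]] <- import_network(f, "edgelist_csv")
  }
  rep_s <- suppressWarnings(crucial_disease_report(
    g, bands, seed = derive_seed(1L, 10L + match(s, c("male", "female")))))

  message(sprintf("%s: hubs: %s", s, paste(rep_s$hubs$code, collapse = ", ")))
  message(sprintf("%s: %d communities (modularity %.3f), roots: %s", s,
                  rep_s$communities$n_communities, rep_s$communities$modularity,
                  paste(rep_s$roots$root, collapse = ", ")))
  message(sprintf("%s: %d burst diseases, cores: %s", s,
                  length(unique(rep_s$bursts$bursts$code)),
                  if (length(rep_s$cores)) paste(rep_s$cores, collapse = ", ") else "(none)"))

  planted_hubs <- truth$hub_set
  message(sprintf("%s: planted hubs in top-10: %d of %d", s,
                  sum(planted_hubs %in% rep_s$hubs$code), length(planted_hubs)))

  out_rows[[s]] <- data.table(
    sex = s,
    category = c(rep("hub", nrow(rep_s$hubs)), rep("root", nrow(rep_s$roots)),
                 rep("burst", length(unique(rep_s$bursts$bursts$code))),
                 rep("core", length(rep_s$cores))),
    code = c(rep_s$hubs$code, rep_s$roots$root,
             unique(rep_s$bursts$bursts$code), rep_s$cores))
  fwrite(rep_s$bursts$trajectories,
         sprintf("results/burst_trajectories_%s.csv", s))
}
fwrite(rbindlist(out_rows), "results/crucial_diseases.csv")
message("wrote results/crucial_diseases.csv and burst trajectory tables")
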