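#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# The real hospital-network diagnosis database behind this analysis is
# access-restricted, so the workflow runs on a synthetic cohort with the
# same structure: adults of both sexes, 2013-2021 outpatient/inpatient visit
# histories, an index T2DM code, and ~120 candidate comorbidity codes with
# four planted co-occurrence clusters and two planted hub conditions.

suppressMessages(library(mmnet))

spec <- synthetic_spec(n_patients = 5000, n_conditions = 120, n_clusters = 4,
                       cluster_effect = 4, hub_conditions = c(1L, 2L), seed = 1L)
sim <- generate_synthetic_cohort(spec, dir = "scratch/synthetic")

message(sprintf("simulated %d patients, %d catalog codes, %d diagnosis events",
                nrow(sim$population), nrow(sim$catalog), nrow(sim$events)))
message(sprintf("planted: %d clusters over %d comorbidity codes; hubs: %s",
                spec$n_clusters, spec$n_conditions - 1,
                paste(sim$truth$hub_set, collapse = ", ")))
message("wrote events/patients/catalog/truth under scratch/synthetic/")
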