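#!/usr/bin/env Rscript
# Stage 2: build the analyzable cohort.
#
# Applies the eligibility rule (every calendar year between first and last
# appearance needs >= 3 outpatient visits or >= 1 hospitalization), sets the
# index date to the earliest T2DM code, computes mean age (average of age at
# index and at last visit), assigns the six age strata, and selects the
# condition universe: ICD-10 chapters 1-14, prevalence >= 1%, post-index
# diagnoses only.

suppressMessages({library(mmnet); library(data.table)})

loaded <- load_records("scratch/synthetic/events.csv",
                       "scratch/synthetic/patients.csv",
                       "scratch/synthetic/catalog.csv")
elig <- apply_eligibility(loaded$events, loaded$patients)
message(sprintf("eligibility: %d of %d patients retained (%d excluded)",
                nrow(elig$eligible), nrow(loaded$patients), nrow(elig$exclusions)))
if (nrow(elig$exclusions)) print(elig$exclusions[, .N, by = reason])

ia <- compute_index_and_age(loaded$events, elig$eligible)
cohort <- ia$cohort
sel <- select_conditions(loaded$events, cohort, loaded$catalog)

message(sprintf("cohort: %d patients (%d male / %d female), universe: %d conditions",
                nrow(cohort), sum(cohort$sex == "male"), sum(cohort$sex == "female"),
                nrow(sel$universe)))
message(sprintf("multimorbid patients (>=1 chronic + >=1 other condition): %d (%.1f%%)",
                sum(sel$multimorbid$multimorbid),
                100 * mean(sel$multimorbid$multimorbid)))

dir.create("scratch/cohort", recursive = TRUE, showWarnings = FALSE)
fwrite(cohort, "scratch/cohort/cohort.csv")
fwrite(sel$condition_sets, "scratch/cohort/condition_sets.csv")
fwrite(sel$universe, "scratch/cohort/universe.csv")

dir.create("results", showWarnings = FALSE)
summary_dt <- cohort[, .(patients = .N, mean_age = round(mean(mean_age), 1)),
                     by = .(sex, age_stratum)][order(sex, age_stratum)]
fwrite(summary_dt, "results/cohort_summary.csv")
message("wrote results/cohort_summary.csv")
print(summary_dt)
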