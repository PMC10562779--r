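# mmnet — multimorbidity networks for type 2 diabetes comorbidities

`mmnet` builds and analyses sex- and age-specific multimorbidity networks
from patient-level ICD-10 diagnosis records of a type 2 diabetes (T2DM)
cohort, and identifies the *crucial diseases* that shape the comorbidity
landscape. It is aimed at epidemiologists and biostatisticians working
with longitudinal claims/EMR-style diagnosis data.

The core model: for conditions *i*, *j* with patient counts c_i, c_j,
co-occurrence count c_ij and cohort size N,

    SCI_ij = c_ij / sqrt(c_i * c_j)                       (edge weight)
    Phi_ij = (c_ij*N - c_i*c_j) / sqrt(c_i*c_j*(N-c_i)*(N-c_j))
    t_ij   = Phi_ij * sqrt(c_ij - 2) / sqrt(1 - Phi_ij^2)

The Salton cosine index (SCI) weights edges because it is invariant to
sample size. Its cut-off is calibrated against the phi screen: with q =
number of pairs with c_ij > 0 and e = number of pairs passing both t >
2.58 (two-sided p < 0.01) and c_ij > mean(c_ij), the network keeps exactly
the e highest-SCI pairs (ties included) — as many edges as there are
significantly, positively correlated pairs.

On the resulting networks the package computes degree, weighted degree,
density, closeness and harmonic centrality; identifies **hub** diseases
(top-10 PageRank), **root** diseases (maximum eigenvector centrality per
Louvain community), **burst** diseases (degree growth ≥ 6 between adjacent
age strata) and **core** diseases (their intersection); tracks degree
trends on cumulative yearly networks; and quantifies robustness via
single-node removal and random edge deletion (1%/3%/5% × 3 replicates).

Real clinical databases of this kind are access-restricted, so the package
includes a synthetic EMR generator with planted co-occurrence clusters and
hub conditions; the planted truth makes every stage testable end to end.

## Worked example

```r
library(mmnet)

spec <- synthetic_spec(n_patients = 5000, n_conditions = 120,
                       n_clusters = 4, cluster_effect = 4,
                       hub_conditions = c(1L, 2L), seed = 1L)
sim    <- generate_synthetic_cohort(spec)
elig   <- apply_eligibility(sim$events, sim$population)
cohort <- compute_index_and_age(sim$events, elig$eligible)$cohort
sel    <- select_conditions(sim$events, cohort, sim$catalog)

nets <- build_stratified_networks(cohort, sel$condition_sets,
                                  sel$universe$code,
                                  chronic_codes = sel$chronic_codes)
g <- nets[["male:global"]]$network
summarize_network(g)[c("n_nodes", "n_edges", "density")]
#> $n_nodes [1] 119   $n_edges [1] 1333   $density [1] 0.1898590

identify_hub_diseases(g, k = 5)$code
#> [1] "J69"   "F31"   "H31"   "K65.1" "K76"
```

The two planted hubs (`F31`, `J69` under this seed) surface at the top of
the PageRank ranking, and removing one of them is what hurts the network
most: in the full workflow the removal of `J69` cuts the male network's
average harmonic centrality by 3.2%, against ≤ 1% for typical nodes —
the signature of a gateway comorbidity.

The complete analysis is scripted as a numbered workflow:

```sh
Rscript analysis/01_simulate_cohort.R   # synthetic cohort -> scratch/
Rscript analysis/02_build_cohort.R      # eligibility, index date, universe
Rscript analysis/03_build_networks.R    # SCI networks, global + age strata
Rscript analysis/04_network_metrics.R   # per-node structural metrics
Rscript analysis/05_crucial_diseases.R  # hubs, roots, bursts, cores
Rscript analysis/06_temporal_trends.R   # seven cumulative yearly networks
Rscript analysis/07_perturbation.R      # node/edge perturbation
```

Each stage prints what it found and writes summary tables under
`results/`; intermediate data lives under `scratch/`. See
`vignettes/multimorbidity-networks.Rmd` for the methods, parameter
choices and known limitations.

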