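---
title: "Multimorbidity networks for T2DM comorbidities: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimorbidity networks for T2DM comorbidities: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Patients with type 2 diabetes mellitus (T2DM) rarely live with a single
comorbidity: conditions arrive in correlated clusters, and some conditions
act as gateways to many others. `mmnet` implements a network view of this
multimorbidity. Nodes are ICD-10 coded conditions observed in a T2DM cohort
after each patient's first diabetes diagnosis; edges connect conditions that
co-occur in the same patients more often than chance; and a small set of
*crucial diseases* — hubs, roots, and bursts — is extracted from the
networks' structure, per sex, together with their temporal trends and a
perturbation-based robustness assessment.

Because clinical diagnosis databases of this kind are access-restricted,
the package ships a synthetic EMR generator that reproduces the *structure*
of such data (visit histories, index dates, sex and age strata, planted
co-occurrence clusters and hubs). All analyses, tests and examples run on
synthetic cohorts; the pipeline itself is agnostic to where the CSV inputs
come from.

## Cohort definitions

* **Eligibility.** A patient is retained when *every* calendar year from
  their first to last appearance in the records contains at least three
  outpatient visits or at least one hospitalization. We interpret
  "annually" as every spanned calendar year inclusive of the partial first
  and last years; `apply_eligibility(exempt_partial_years = TRUE)` relaxes
  this for sensitivity analyses. Patients with conflicting sex records or
  missing sex/birth data are excluded with reason codes.
* **Index date and age.** The index date is the earliest T2DM-coded event.
  Age is the mean of the exact fractional age (days/365.25) at the index
  date and at the last visit. The six age strata — `<40`, `40-49`, `50-59`,
  `60-69`, `70-79`, `>=80` — are left-closed, so an age of exactly 40 falls
  in `40-49`.
* **Condition universe.** Only diagnoses on or after the index date count.
  Analyzable codes come from ICD-10 chapters 1–14, excluding the bare T2DM
  index code (subdivided complication codes are ordinary conditions when
  the catalog carries them). A bare three-character code whose stem has
  both chronic and acute four-character subdivisions defers to those
  subdivisions. Codes below 1% cohort prevalence are dropped; the
  prevalence filter is computed on the pooled cohort (both sexes) so all
  strata share one condition universe — sex-specific networks are then
  subsets of it, which is the only reading consistent with reporting one
  universe and two sex networks of different size.
* **Multimorbidity gate.** Multimorbidity means one chronic condition plus
  at least one other condition. `contingency_counts(chronic_codes = ...)`
  implements this at the patient level: patients without any chronic
  retained condition contribute to marginal counts $c_i$ but not to pair
  counts $c_{ij}$. Single-condition patients need no special casing — they
  have no pairs.

## Edge statistics and the calibrated cut-off

For each unordered pair of conditions $(i, j)$ with marginal counts $c_i,
c_j$, co-occurrence count $c_{ij}$, and stratum size $N$:

$$\mathrm{SCI}_{ij} = \frac{c_{ij}}{\sqrt{c_i\,c_j}}, \qquad
\Phi_{ij} = \frac{c_{ij}N - c_i c_j}{\sqrt{c_i c_j (N - c_i)(N - c_j)}},
\qquad
t_{ij} = \frac{\Phi_{ij}\sqrt{c_{ij} - 2}}{\sqrt{1 - \Phi_{ij}^2}}.$$

The Salton cosine index (SCI) is used as the edge weight because it is
invariant to sample size: duplicating every patient record leaves every SCI
unchanged (this is asserted to 1e-12 in the test suite). Note that $\Phi$,
being a correlation, is *also* invariant under exact duplication; the
sample-size sensitivity of the phi route lives in the $t$ statistic, whose
degrees of freedom grow with $c_{ij}$, and hence in which pairs pass a
significance screen.

Since even negatively correlated pairs have positive SCI, the cut-off is
calibrated against the phi screen in four steps: (1) compute SCI and
$\Phi$ for all pairs; (2) $q$ = number of pairs with $c_{ij} > 0$; (3) $e$
= number of pairs with $t > 2.58$ (two-sided $p < 0.01$) **and** $c_{ij} >
\sum c_{ij} / q$; (4) the SCI cut-off is the $e$-th largest SCI among the
$q$ pairs, and every pair with SCI at or above it becomes an edge. The
principle is that the SCI network retains exactly as many edges as there
are significantly, positively correlated pairs — since $t > 2.58$ forces
$\Phi > 0$, negative correlations are excluded implicitly.

Numerical and degenerate-input choices, each covered by a test:

* $t$ is set to 0 when $c_{ij} \le 2$ (the degrees-of-freedom term is
  undefined; such sparse pairs fail the screen), and to signed infinity
  when $|\Phi| = 1$.
* The $\bar c$ screen uses $\sum c_{ij}/q$ over the $q$ pairs with
  $c_{ij} > 0$, matching the definition of $q$.
* Pairs with $c_i = N$ or $c_j = N$ have an undefined $\Phi$ denominator;
  they are flagged and excluded from calibration rather than silently
  yielding NaN.
* The cut-off keeps ties: every pair with SCI $\ge$ the $e$-th largest
  value is retained, so the retained count can exceed $e$ only by ties.
* The degrees-of-freedom term is written with $c_{ij}$, the pair's
  co-occurrence count, not $N$. We implement it as stated. A consequence
  worth knowing: at moderate cohort sizes the screen is *conservative* —
  under independence the pass rate sits well below the nominal 0.5%
  one-tail level, because $\sqrt{c_{ij}-2} \ll \sqrt{N}$. The generator
  calibration test asserts exactly this (pass rate at or below nominal, and
  within-cluster $\Phi$ centred on zero at `cluster_effect = 1`).

Strata: one network per non-empty sex × age band (up to twelve) plus one
global network per sex, each with counts, statistics and cut-off computed
within the stratum.

## Network metrics

Degree, SCI-weighted degree, density $2m/(n(n-1))$, closeness and harmonic
centrality. Shortest paths use unweighted hop counts: the SCI is a
similarity, not a travel cost, and no weight-to-distance transform is part
of the model. Because the stratified networks are not all connected,
harmonic centrality $\sum_{u \ne v} 1/d(u,v)$ (unreachable pairs
contribute 0) replaces closeness for node-level reporting; closeness is
still computed, within the largest connected component, for network-level
summaries. Average harmonic centrality is reported both raw and normalized
by $n-1$; the normalized version is used for cross-stratum comparison and
for perturbation percent changes, since strata differ in size.

## Crucial diseases

* **Hubs** — the top-10 nodes by PageRank (damping 0.85, the conventional
  default) on the SCI-weighted global sex network, each undirected edge
  acting as two directed arcs with transition probability proportional to
  weight.
* **Roots** — communities come from weighted-modularity Louvain
  (resolution 1, best of 20 seeded restarts); within each community, the
  node maximizing eigenvector centrality on the community's *induced
  weighted subgraph* is its root. Hubs and communities are computed on the
  global per-sex networks; the age-stratified networks serve only the
  burst analysis.
* **Bursts** — a condition whose degree grows by 6 or more between
  *adjacent* age bands (inclusive threshold); a condition absent from a
  band's network has degree 0 there. Comparisons are only between
  consecutive bands.
* **Cores** — the per-sex intersection of the hub, root and burst code
  sets.
* Ties anywhere (top-10 boundaries, argmax) are broken by higher weighted
  degree, then lexicographically smaller code, after rounding scores to 10
  significant digits so floating-point noise cannot override the rule;
  ties are flagged in the output.

**Temporal trends.** The continuity cohort holds patients whose index date
falls in the first study year (2013) and who meet the visit quota in every
study year. For each year from the 2015 baseline through 2021, a network is
built from all post-index diagnoses up to that year's end — seven
cumulative networks — and each condition's degree is tracked.

## Perturbation analyses

* **Node removal**: each crucial disease is removed independently (the
  network is restored between removals); nodes isolated by the removal are
  dropped, the summary metrics recomputed, and signed percent changes
  reported — notably for normalized average harmonic centrality. Removal
  operates on the built network; cut-offs are not recalibrated, matching a
  perturbation (rather than re-estimation) reading.
* **Edge removal**: `round(level × m)` edges are deleted uniformly without
  replacement at levels 1%, 3% and 5%, three replicates each, every
  replicate's seed derived deterministically from the master seed; the
  overlap between the perturbed and original top-10 PageRank lists
  measures hub stability. Levels rounding to zero removals are skipped
  with a warning.

## The synthetic generator

Each patient activates each of $k$ planted clusters independently with
probability $a = 0.3$; an active cluster multiplies the baseline
probability $p_j$ of its member conditions by the `cluster_effect` $e$
(capped at 0.9). At $e = 1$ all conditions are independent, which is the
calibration regime for type-I-error checks. Hub conditions respond to
*any* active cluster and take the top of the baseline range, wiring them
across the whole universe — consequently a hub has no single true cluster,
and planted-partition recovery (adjusted Rand index) is evaluated over
non-hub network nodes, with hubs carrying pseudo-cluster 0 in the planted
truth. Visits are Poisson (mean 6 outpatient visits per patient-year) plus
Bernoulli hospitalizations (0.15/year), so eligibility filtering is
non-trivial but mostly passed; half of the patients enter in the first
study year so the continuity cohort is well populated; dates are uniform
within years, at or after the index date; one event row carries one code.
An optional per-condition logistic age effect (default off) lets users
plant age-dependent onsets for burst studies.

The defaults were fixed by a design-time power and separability analysis
rather than by prevalence calibration to any real catalog. Under the
model, a condition's marginal prevalence is $m = p\,(a e + 1 - a)$, a
within-cluster pair's expected SCI is $\frac{a e^2 + 1 - a}{a e + 1 - a}
\sqrt{p_i p_j}$, and a cross-cluster pair's is $(a e + 1 - a)\sqrt{p_i
p_j}$ — a constant ratio of about 1.52 at $e = 4$, $a = 0.3$. Two
constraints follow. First, with the as-printed $t$ statistic, a
within-cluster pair at $N = 5000$ passes $t > 2.58$ only when both
baseline prevalences are roughly above 0.115. Second, for the calibrated
cut-off to rank within-cluster pairs ahead of cross-cluster ones, the
prevalence spread must stay below that 1.52 separation factor. The default
baseline range 0.10–0.20 satisfies both, which is why planted clusters and
hubs are recoverable (ARI ≥ 0.9, hub recall ≥ 0.8) at `cluster_effect = 4`
and 5,000 patients.

What the generator does *not* emulate: real ICD-10 semantics or prevalence
profiles, mortality and censoring, coding practice drift, care-seeking
correlation between conditions beyond the latent clusters, and negatively
associated condition pairs. Passing recovery tests therefore demonstrates
that the pipeline recovers block-structured co-occurrence planted under
this mechanism — not that it would recover the comorbidity structure of
any particular real population.

## Problem sizes and reproducibility

The analysis scripts under `analysis/` run at 5,000 patients, 120 catalog
codes and four clusters; the test suite uses 80–5,000 patients depending
on what a check needs (closed-form examples at toy size, oracle
equivalence at ≤ 200 patients and ≤ 60 conditions over 20 fixtures,
recovery at 5,000 patients over 20 seeds). These sizes were chosen so each
property is measured with adequate Monte-Carlo precision while the whole
suite stays quick to run. Every stochastic stage draws from its own seed,
derived deterministically from one master seed, and identical
configurations produce byte-identical outputs — the pipeline writes a
manifest from which a run can be reproduced exactly (the manifest stores
only basenames of paths, so reruns in different directories compare equal
byte for byte).

## Known limitations

* The Louvain and PageRank implementations come from igraph; restarted
  Louvain with a fixed seed sequence makes partitions reproducible but not
  globally optimal.
* The cut-off calibration inherits the conservatism of the as-printed
  $t$ statistic at small $N$; at the cohort sizes such analyses target
  (hundreds of thousands of patients) this has no practical effect, but
  desk-scale replications should expect sparser networks than naive
  phi-screen intuition suggests.
* Closeness on disconnected graphs is reported for the largest component
  only, with a disconnectedness flag.
* Perturbation percent changes are undefined (NA) when a baseline metric
  is zero.
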