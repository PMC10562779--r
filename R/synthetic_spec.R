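# Specification object for the synthetic EMR generator.

#' Specify a synthetic T2DM cohort
#'
#' Collects every parameter of the synthetic electronic-medical-record
#' generator into a validated specification. The generator emulates the
#' structure of a hospital-network diagnosis database: adult patients of both
#' sexes, outpatient/inpatient visit histories over a span of calendar years,
#' an index T2DM code, and a universe of candidate comorbidity codes with
#' planted co-occurrence clusters and planted high-connectivity hubs.
#'
#' Conditions other than the index code are partitioned into `n_clusters`
#' latent clusters. Each patient independently "activates" each cluster with
#' probability `cluster_activation`; an active cluster multiplies the
#' baseline probability of each member condition by `cluster_effect`
#' (`cluster_effect = 1` therefore means full independence). Hub conditions
#' respond to *any* active cluster, which wires them across the whole
#' condition universe.
#'
#' @param n_patients Number of patients (positive integer).
#' @param sex_ratio Fraction of males, in \[0, 1\].
#' @param n_conditions Total number of catalog codes, including the single
#'   T2DM index code (so `n_conditions - 1` candidate comorbidities).
#' @param n_clusters Number of planted co-occurrence clusters.
#' @param baseline_prevalence_range Length-2 probability vector; per-condition
#'   baseline prevalences are drawn uniformly from this range.
#' @param cluster_effect Multiplier (>= 1 typical) on a member condition's
#'   probability when its cluster is active; 1 = independence.
#' @param hub_conditions Integer indices (into the comorbidity conditions,
#'   i.e. 1..n_conditions-1) of planted hubs.
#' @param years Length-2 inclusive calendar-year range, spanning >= 2 years.
#' @param age_range Length-2 inclusive age bounds, lower bound >= 18.
#' @param seed Integer seed; identical specs (including seed) give
#'   byte-identical output.
#' @param cluster_activation Per-patient, per-cluster activation probability.
#' @param outpatient_rate Mean outpatient visits per patient-year (Poisson).
#' @param inpatient_prob Probability of a hospitalization in a patient-year.
#' @param chronic_fraction Fraction of catalog codes flagged chronic.
#' @param prob_cap Upper cap on any per-patient condition probability.
#' @param age_effects Optional named numeric vector of logistic age-onset
#'   slopes, names = comorbidity condition indices; default none (ages do not
#'   influence condition onset).
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_patients = 2000,
                           sex_ratio = 0.5,
                           n_conditions = 120,
                           n_clusters = 4,
                           baseline_prevalence_range = c(0.10, 0.20),
                           cluster_effect = 4,
                           hub_conditions = c(1L, 2L),
                           years = c(2013, 2021),
                           age_range = c(18, 90),
                           seed = 1L,
                           cluster_activation = 0.3,
                           outpatient_rate = 6,
                           inpatient_prob = 0.15,
                           chronic_fraction = 0.6,
                           prob_cap = 0.9,
                           age_effects = NULL) {
  spec <- list(
    n_patients = n_patients, sex_ratio = sex_ratio,
    n_conditions = n_conditions, n_clusters = n_clusters,
    baseline_prevalence_range = baseline_prevalence_range,
    cluster_effect = cluster_effect, hub_conditions = as.integer(hub_conditions),
    years = as.integer(years), age_range = age_range, seed = as.integer(seed),
    cluster_activation = cluster_activation, outpatient_rate = outpatient_rate,
    inpatient_prob = inpatient_prob, chronic_fraction = chronic_fraction,
    prob_cap = prob_cap, age_effects = age_effects
  )
  class(spec) <- "synthetic_spec"
  validate_synthetic_spec(spec)
  spec
}

#' Validate a synthetic cohort specification
#'
#' @param spec A `synthetic_spec` object.
#' @return `spec`, invisibly, if valid; otherwise an error naming the
#'   offending field.
#' @export
validate_synthetic_spec <- function(spec) {
  fail <- function(field, why) {
    stop(sprintf("invalid synthetic_spec field '%s': %s", field, why), call. = FALSE)
  }
  chk_scalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!chk_scalar(spec$n_patients) || spec$n_patients < 1 ||
      spec$n_patients != round(spec$n_patients))
    fail("n_patients", "must be a positive integer")
  if (!chk_scalar(spec$sex_ratio) || spec$sex_ratio < 0 || spec$sex_ratio > 1)
    fail("sex_ratio", "must be a probability in [0,1]")
  if (!chk_scalar(spec$n_conditions) || spec$n_conditions < 2 ||
      spec$n_conditions != round(spec$n_conditions))
    fail("n_conditions", "must be an integer >= 2 (index code plus comorbidities)")
  if (!chk_scalar(spec$n_clusters) || spec$n_clusters < 1 ||
      spec$n_clusters > spec$n_conditions)
    fail("n_clusters", "must be a positive integer <= n_conditions")
  bpr <- spec$baseline_prevalence_range
  if (!is.numeric(bpr) || length(bpr) != 2L || any(bpr < 0) || any(bpr > 1) ||
      bpr[1] > bpr[2])
    fail("baseline_prevalence_range", "must be an increasing pair of probabilities")
  if (!chk_scalar(spec$cluster_effect) || spec$cluster_effect <= 0)
    fail("cluster_effect", "must be a positive multiplier")
  n_comorb <- spec$n_conditions - 1L
  if (length(spec$hub_conditions) &&
      (any(spec$hub_conditions < 1) || any(spec$hub_conditions > n_comorb)))
    fail("hub_conditions", sprintf("indices must lie in 1..%d", n_comorb))
  if (length(spec$years) != 2L || spec$years[1] > spec$years[2] ||
      diff(spec$years) < 1)
    fail("years", "must span at least 2 calendar years")
  if (length(spec$age_range) != 2L || spec$age_range[1] < 18 ||
      spec$age_range[1] > spec$age_range[2])
    fail("age_range", "bounds must satisfy 18 <= lower <= upper")
  if (!chk_scalar(spec$seed)) fail("seed", "must be a single integer")
  for (f in c("cluster_activation", "inpatient_prob", "chronic_fraction", "prob_cap")) {
    if (!chk_scalar(spec[[f]]) || spec[[f]] < 0 || spec[[f]] > 1)
      fail(f, "must be a probability in [0,1]")
  }
  if (!chk_scalar(spec$outpatient_rate) || spec$outpatient_rate < 0)
    fail("outpatient_rate", "must be a non-negative rate")
  if (!is.null(spec$age_effects)) {
    if (!is.numeric(spec$age_effects) || is.null(names(spec$age_effects)))
      fail("age_effects", "must be a named numeric vector (condition index -> slope)")
    idx <- suppressWarnings(as.integer(names(spec$age_effects)))
    if (anyNA(idx) || any(idx < 1) || any(idx > n_comorb))
      fail("age_effects", sprintf("names must be condition indices in 1..%d", n_comorb))
  }
  invisible(spec)
}
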