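# Synthetic EMR generator: condition catalog, population, planted
# co-occurrence structure, and dated diagnosis events.
#
# The generator stands in for a restricted hospital diagnosis database. It is
# first-class, tested code: downstream parameter-recovery tests depend on the
# planted truth it returns.

# ICD-10-like chapter blocks (chapter number, letter, numeric range). Chapters
# 1-14 describe conditions rather than symptoms and are the analyzable set.
.chapter_blocks <- data.frame(
  chapter = 1:14,
  letter  = c("A", "C", "D", "E", "F", "G", "H", "H", "I", "J", "K", "L", "M", "N"),
  lo      = c(0, 0, 50, 0, 0, 0, 0, 60, 0, 0, 0, 0, 0, 0),
  hi      = c(99, 97, 89, 90, 99, 99, 59, 95, 99, 99, 93, 99, 99, 99)
)

T2DM_INDEX_CODE <- "E11"

#' Generate a synthetic condition catalog
#'
#' Produces `n_conditions` distinct ICD-10-shaped codes (letter + two digits,
#' a quarter of them with a fourth-character subcode), each assigned a chapter
#' in 1-14 and a chronic/acute flag. The first row is always the T2DM index
#' code `E11`, flagged `is_t2dm_index` and excluded from the comorbidity
#' universe; the remaining rows are the candidate comorbidities, in the order
#' referenced by `hub_conditions` / `age_effects` indices.
#'
#' @param spec A [synthetic_spec()].
#' @return A `data.table` with columns `code`, `chapter`, `chronic_flag`,
#'   `granularity` (`three_char` / `four_plus_char`), `is_t2dm_index`.
#' @export
generate_condition_catalog <- function(spec) {
  validate_synthetic_spec(spec)
  set.seed(derive_seed(spec$seed, 1L))
  n_comorb <- spec$n_conditions - 1L

  pool <- do.call(rbind, lapply(seq_len(nrow(.chapter_blocks)), function(i) {
    b <- .chapter_blocks[i, ]
    data.frame(stem = sprintf("%s%02d", b$letter, b$lo:b$hi), chapter = b$chapter)
  }))
  pool <- pool[pool$stem != T2DM_INDEX_CODE, ]
  if (n_comorb > nrow(pool)) {
    stop("invalid synthetic_spec field 'n_conditions': more conditions than available code stems",
         call. = FALSE)
  }
  picked <- pool[sample.int(nrow(pool), n_comorb), ]
  has_sub <- stats::runif(n_comorb) < 0.25
  code <- ifelse(has_sub,
                 sprintf("%s.%d", picked$stem, sample(0:9, n_comorb, replace = TRUE)),
                 picked$stem)

  catalog <- data.table::data.table(
    code = c(T2DM_INDEX_CODE, code),
    chapter = c(4L, picked$chapter),
    chronic_flag = c(TRUE, stats::runif(n_comorb) < spec$chronic_fraction),
    granularity = c("three_char",
                    ifelse(has_sub, "four_plus_char", "three_char")),
    is_t2dm_index = c(TRUE, rep(FALSE, n_comorb))
  )
  stopifnot(!anyDuplicated(catalog$code))
  catalog[]
}

#' Generate a synthetic patient population
#'
#' Draws `n_patients` patients with unique ids, sex by `sex_ratio`, and birth
#' dates chosen so that every patient's age stays within `age_range` over the
#' whole study-year span (hence always >= 18 at any visit).
#'
#' @param spec A [synthetic_spec()].
#' @return A `data.table` with columns `patient_id`, `sex`, `birth_date`.
#' @export
generate_population <- function(spec) {
  validate_synthetic_spec(spec)
  set.seed(derive_seed(spec$seed, 2L))
  n <- spec$n_patients
  span <- spec$years[2] - spec$years[1]
  lo <- spec$age_range[1]
  hi <- max(lo, spec$age_range[2] - span)
  age_at_start <- stats::runif(n, lo, hi)
  study_start <- as.Date(sprintf("%d-01-01", spec$years[1]))
  data.table::data.table(
    patient_id = sprintf("P%06d", seq_len(n)),
    sex = ifelse(stats::runif(n) < spec$sex_ratio, "male", "female"),
    birth_date = study_start - round(age_at_start * 365.25)
  )
}

#' Draw the latent-factor patient-by-condition incidence matrix
#'
#' The core of the generator: each patient activates each planted cluster
#' independently with probability `cluster_activation`; an active cluster
#' multiplies the baseline probability of its member conditions by
#' `cluster_effect`. Hub conditions respond to *any* active cluster and get
#' the top of the baseline prevalence range, which wires them across
#' clusters. At `cluster_effect = 1` all conditions are independent.
#'
#' @param spec A [synthetic_spec()].
#' @param catalog Optional catalog from [generate_condition_catalog()] (same
#'   spec); generated if omitted.
#' @param population Optional population from [generate_population()]; only
#'   needed (and generated if omitted) when `age_effects` are present.
#' @return A list: `incidence` (0/1 matrix, patients x comorbidity codes),
#'   `p_base` (baseline prevalences), `truth` (a `PlantedTruth` list with
#'   `cluster_assignment` — hubs carry pseudo-cluster 0 —, `hub_set`, and
#'   `pairwise_target_association` for within-cluster pairs).
#' @export
simulate_condition_matrix <- function(spec, catalog = NULL, population = NULL) {
  validate_synthetic_spec(spec)
  if (is.null(catalog)) catalog <- generate_condition_catalog(spec)
  comorb <- catalog[!catalog$is_t2dm_index, ]
  ncond <- nrow(comorb)
  if (ncond != spec$n_conditions - 1L) {
    stop("consistency error: catalog does not match spec (comorbidity count)", call. = FALSE)
  }
  need_ages <- !is.null(spec$age_effects)
  if (need_ages && is.null(population)) population <- generate_population(spec)

  set.seed(derive_seed(spec$seed, 3L))
  n <- spec$n_patients
  k <- spec$n_clusters
  a <- spec$cluster_activation
  eff <- spec$cluster_effect

  cl <- rep_len(seq_len(k), ncond)
  hubs <- spec$hub_conditions
  cl[hubs] <- 0L

  p_base <- stats::runif(ncond, spec$baseline_prevalence_range[1],
                         spec$baseline_prevalence_range[2])
  p_base[hubs] <- spec$baseline_prevalence_range[2]

  Z <- matrix(stats::rbinom(n * k, 1L, a), nrow = n, ncol = k)
  any_active <- rowSums(Z) > 0L

  P <- matrix(rep(p_base, each = n), nrow = n, ncol = ncond)
  for (j in seq_len(ncond)) {
    active <- if (cl[j] == 0L) any_active else Z[, cl[j]] == 1L
    P[active, j] <- P[active, j] * eff
  }
  if (need_ages) {
    mid_study <- as.Date(sprintf("%d-07-01", floor(mean(spec$years))))
    age <- as.numeric(mid_study - population$birth_date) / 365.25
    for (nm in names(spec$age_effects)) {
      j <- as.integer(nm)
      P[, j] <- P[, j] * 2 * stats::plogis(spec$age_effects[[nm]] * (age - 55) / 10)
    }
  }
  P <- pmin(P, spec$prob_cap)
  M <- matrix(stats::rbinom(length(P), 1L, as.vector(P)), nrow = n, ncol = ncond)
  colnames(M) <- comorb$code

  # Expected excess co-occurrence for non-hub within-cluster pairs, from the
  # model: marginal m = p(a*eff + 1 - a); joint = p_i p_j (a*eff^2 + 1 - a).
  m_marg <- p_base * (a * eff + (1 - a))
  assoc <- data.table::rbindlist(lapply(seq_len(k), function(g) {
    idx <- which(cl == g)
    if (length(idx) < 2L) return(NULL)
    pr <- t(utils::combn(idx, 2L))
    data.table::data.table(
      code_i = comorb$code[pr[, 1]],
      code_j = comorb$code[pr[, 2]],
      excess = p_base[pr[, 1]] * p_base[pr[, 2]] * (a * eff^2 + (1 - a)) -
        m_marg[pr[, 1]] * m_marg[pr[, 2]]
    )
  }))

  list(
    incidence = M,
    p_base = stats::setNames(p_base, comorb$code),
    truth = list(
      cluster_assignment = stats::setNames(cl, comorb$code),
      hub_set = comorb$code[hubs],
      pairwise_target_association = assoc
    )
  )
}

#' Generate dated diagnosis events with planted co-occurrence structure
#'
#' Turns the latent-factor incidence matrix into a long event table. Every
#' patient gets a T2DM index event in their entry year, Poisson numbers of
#' outpatient follow-up visits per year plus Bernoulli hospitalizations (all
#' carrying the index code), and one dated onset event per acquired
#' comorbidity, placed on or after the index date. Half of the patients enter
#' in the first study year so cumulative yearly networks are non-trivial.
#'
#' @param population From [generate_population()] (same spec).
#' @param catalog From [generate_condition_catalog()] (same spec).
#' @param spec The [synthetic_spec()] both were generated from.
#' @return A list: `events` (`data.table` with `patient_id`, `visit_date`,
#'   `visit_type`, `icd10_code`) and `truth` (the `PlantedTruth` list).
#' @export
generate_diagnosis_events <- function(population, catalog, spec) {
  validate_synthetic_spec(spec)
  if (nrow(population) != spec$n_patients) {
    stop("consistency error: population was not generated from this spec (n_patients mismatch)",
         call. = FALSE)
  }
  if (nrow(catalog) != spec$n_conditions || sum(catalog$is_t2dm_index) != 1L) {
    stop("consistency error: catalog was not generated from this spec", call. = FALSE)
  }
  sim <- simulate_condition_matrix(spec, catalog, population)
  M <- sim$incidence

  set.seed(derive_seed(spec$seed, 4L))
  n <- spec$n_patients
  years <- seq(spec$years[1], spec$years[2])
  ny <- length(years)

  entry_year <- sample(years, n, replace = TRUE,
                       prob = c(0.5, rep(0.5 / (ny - 1), ny - 1)))
  year_start <- function(y) as.Date(sprintf("%d-01-01", y))
  year_len <- function(y) as.integer(as.Date(sprintf("%d-12-31", y)) - year_start(y)) + 1L
  index_date <- year_start(entry_year) +
    floor(stats::runif(n) * (year_len(entry_year) - 1L))

  rand_date <- function(y, floor_date = NULL) {
    # uniform date within calendar year y, optionally at/after floor_date
    lo <- year_start(y)
    if (!is.null(floor_date)) lo <- pmax(lo, floor_date)
    ndays <- as.integer(year_start(y + 1L) - lo)
    lo + floor(stats::runif(length(y)) * ndays)
  }

  # patient-year grid from entry year to the end of the study window
  grid <- data.table::data.table(
    row = rep(seq_len(n), ny - (entry_year - years[1])),
    year = unlist(lapply(seq_len(n), function(i) seq(entry_year[i], years[ny])))
  )
  data.table::setorder(grid, row, year)
  grid$n_out <- stats::rpois(nrow(grid), spec$outpatient_rate)
  grid$inp <- stats::rbinom(nrow(grid), 1L, spec$inpatient_prob)

  pid <- population$patient_id
  t2dm <- catalog$code[catalog$is_t2dm_index][1]

  idx_events <- data.table::data.table(
    patient_id = pid, visit_date = index_date,
    visit_type = "outpatient", icd10_code = t2dm
  )

  out <- grid[rep(seq_len(nrow(grid)), grid$n_out), c("row", "year")]
  out_floor <- index_date[out$row]
  out_floor[out$year != entry_year[out$row]] <- NA
  out_events <- data.table::data.table(
    patient_id = pid[out$row],
    visit_date = data.table::fifelse(
      is.na(out_floor), rand_date(out$year), rand_date(out$year, out_floor)),
    visit_type = "outpatient", icd10_code = t2dm
  )

  inp <- grid[grid$inp == 1L, c("row", "year")]
  inp_floor <- index_date[inp$row]
  inp_floor[inp$year != entry_year[inp$row]] <- NA
  inp_events <- data.table::data.table(
    patient_id = pid[inp$row],
    visit_date = data.table::fifelse(
      is.na(inp_floor), rand_date(inp$year), rand_date(inp$year, inp_floor)),
    visit_type = "inpatient", icd10_code = t2dm
  )

  has <- which(M == 1L, arr.ind = TRUE)
  onset_year <- entry_year[has[, 1]] +
    floor(stats::runif(nrow(has)) * (years[ny] - entry_year[has[, 1]] + 1L))
  onset_floor <- index_date[has[, 1]]
  onset_floor[onset_year != entry_year[has[, 1]]] <- NA
  cond_events <- data.table::data.table(
    patient_id = pid[has[, 1]],
    visit_date = data.table::fifelse(
      is.na(onset_floor), rand_date(onset_year), rand_date(onset_year, onset_floor)),
    visit_type = ifelse(stats::runif(nrow(has)) < 0.1, "inpatient", "outpatient"),
    icd10_code = colnames(M)[has[, 2]]
  )

  events <- data.table::rbindlist(list(idx_events, out_events, inp_events, cond_events))
  data.table::setorder(events, patient_id, visit_date, icd10_code, visit_type)
  list(events = events[], truth = sim$truth)
}

#' Generate (and optionally write) a complete synthetic cohort
#'
#' Convenience wrapper running catalog, population and event generation from
#' one spec. When `dir` is given, writes `events.csv` (with sex and birth
#' date joined in), `patients.csv`, `catalog.csv` and `truth.json`.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Optional output directory (created if missing).
#' @return A list: `catalog`, `population`, `events`, `truth`, and `paths`
#'   when written.
#' @export
generate_synthetic_cohort <- function(spec, dir = NULL) {
  catalog <- generate_condition_catalog(spec)
  population <- generate_population(spec)
  ev <- generate_diagnosis_events(population, catalog, spec)
  out <- list(catalog = catalog, population = population,
              events = ev$events, truth = ev$truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    events_full <- merge(ev$events, population, by = "patient_id", sort = FALSE)
    data.table::setcolorder(events_full, c("patient_id", "sex", "birth_date",
                                           "visit_date", "visit_type", "icd10_code"))
    paths <- list(
      events = file.path(dir, "events.csv"),
      patients = file.path(dir, "patients.csv"),
      catalog = file.path(dir, "catalog.csv"),
      truth = file.path(dir, "truth.json")
    )
    data.table::fwrite(events_full, paths$events)
    data.table::fwrite(population, paths$patients)
    data.table::fwrite(catalog, paths$catalog)
    jsonlite::write_json(
      list(cluster_assignment = as.list(ev$truth$cluster_assignment),
           hub_set = ev$truth$hub_set,
           pairwise_target_association = ev$truth$pairwise_target_association),
      paths$truth, auto_unbox = TRUE, digits = NA)
    out$paths <- paths
  }
  out
}
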