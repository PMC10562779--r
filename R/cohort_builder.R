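# Cohort construction: record loading, eligibility, index date / mean age,
# and condition selection under the multimorbidity definition.

#' Load diagnosis records, patients and condition catalog from CSV
#'
#' Parses and types the three input tables, validating the schema. Rows with
#' unparseable visit dates are dropped and counted; an empty events file
#' yields an empty table with a warning.
#'
#' @param events_path CSV with at least `patient_id`, `visit_date`,
#'   `visit_type` (`outpatient`/`inpatient`), `icd10_code`.
#' @param patients_path CSV with `patient_id`, `sex`, `birth_date`.
#' @param catalog_path CSV with `code`, `chapter`, `chronic_flag`,
#'   `is_t2dm_index` (optional `granularity`).
#' @param study_window Length-2 Date vector; events outside it are dropped
#'   with a count. Default 2013-01-01 .. 2021-12-31.
#' @return A list: `events`, `patients`, `catalog` (data.tables) and
#'   `n_malformed` (dropped event rows).
#' @export
load_records <- function(events_path, patients_path, catalog_path,
                         study_window = as.Date(c("2013-01-01", "2021-12-31"))) {
  for (p in c(events_path, patients_path, catalog_path)) {
    if (!file.exists(p)) stop(sprintf("input file not found: %s", p), call. = FALSE)
  }
  events <- data.table::fread(events_path, colClasses = list(character = "patient_id"))
  patients <- data.table::fread(patients_path, colClasses = list(character = "patient_id"))
  catalog <- data.table::fread(catalog_path)

  need_ev <- c("patient_id", "visit_date", "visit_type", "icd10_code")
  need_pt <- c("patient_id", "sex", "birth_date")
  need_ct <- c("code", "chapter", "chronic_flag", "is_t2dm_index")
  miss <- setdiff(need_ev, names(events))
  if (nrow(events) > 0 && length(miss)) {
    stop(sprintf("events file missing required column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  miss <- setdiff(need_pt, names(patients))
  if (length(miss)) {
    stop(sprintf("patients file missing required column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  miss <- setdiff(need_ct, names(catalog))
  if (length(miss)) {
    stop(sprintf("catalog file missing required column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }

  n_malformed <- 0L
  if (nrow(events) == 0) {
    warning("events file is empty")
    events <- data.table::data.table(patient_id = character(), visit_date = as.Date(character()),
                                     visit_type = character(), icd10_code = character())
  } else {
    bad_type <- setdiff(unique(events$visit_type), c("outpatient", "inpatient"))
    if (length(bad_type)) {
      stop(sprintf("invalid visit_type value(s): %s; allowed values are: outpatient, inpatient",
                   paste(bad_type, collapse = ", ")), call. = FALSE)
    }
    events[, visit_date := as.Date(visit_date)]
    bad <- is.na(events$visit_date) | events$icd10_code == "" |
      !grepl("^[A-Za-z]", events$icd10_code)
    out_of_window <- !bad & (events$visit_date < study_window[1] |
                               events$visit_date > study_window[2])
    n_malformed <- sum(bad) + sum(out_of_window)
    if (n_malformed > 0) {
      warning(sprintf("dropped %d malformed or out-of-window event row(s)", n_malformed))
    }
    events <- events[!bad & !out_of_window]
  }
  patients[, birth_date := as.Date(birth_date)]
  list(events = events[], patients = patients[], catalog = catalog[],
       n_malformed = n_malformed)
}

#' Apply visit-based eligibility and sex/age completeness rules
#'
#' Retains patients for whom *every* calendar year from their first to last
#' appearance in the records (inclusive) has at least three outpatient visits
#' or at least one hospitalization. Patients with conflicting sex records,
#' missing sex, or missing birth date are excluded with reason codes.
#'
#' @param events Event table from [load_records()].
#' @param patients Patient table from [load_records()].
#' @param exempt_partial_years If `TRUE`, the first and last appearance years
#'   are exempt from the visit quota. Default `FALSE` (the quota applies to
#'   every year in the span).
#' @return A list: `eligible` (patient table, one row per eligible patient)
#'   and `exclusions` (`patient_id`, `reason`).
#' @export
apply_eligibility <- function(events, patients, exempt_partial_years = FALSE) {
  pt <- data.table::as.data.table(patients)
  excl <- list()

  sex_n <- pt[, .(n_sex = data.table::uniqueN(sex)), by = patient_id]
  conflicted <- sex_n$patient_id[sex_n$n_sex > 1]
  if (length(conflicted)) {
    excl$sex <- data.table::data.table(patient_id = conflicted, reason = "conflicting_sex")
  }
  pt <- unique(pt[!patient_id %in% conflicted], by = "patient_id")
  miss_sex <- pt$patient_id[is.na(pt$sex) | !(pt$sex %in% c("male", "female"))]
  miss_age <- pt$patient_id[is.na(pt$birth_date)]
  if (length(miss_sex)) excl$msex <- data.table::data.table(patient_id = miss_sex, reason = "missing_sex")
  if (length(miss_age)) excl$mage <- data.table::data.table(patient_id = setdiff(miss_age, miss_sex), reason = "missing_age")
  pt <- pt[!patient_id %in% c(miss_sex, miss_age)]

  ev <- data.table::as.data.table(events)[patient_id %in% pt$patient_id]
  if (nrow(ev) == 0) {
    no_rec <- pt$patient_id
  } else {
    ev[, year := data.table::year(visit_date)]
    per_year <- ev[, .(
      n_out = sum(visit_type == "outpatient"),
      n_inp = sum(visit_type == "inpatient")
    ), by = .(patient_id, year)]
    span <- per_year[, .(first = min(year), last = max(year)), by = patient_id]
    ok <- merge(per_year, span, by = "patient_id")
    verdict <- ok[, {
      yrs <- if (exempt_partial_years && last > first + 1L) seq(first[1] + 1L, last[1] - 1L)
             else seq(first[1], last[1])
      covered <- year[n_out >= 3L | n_inp >= 1L]
      .(eligible = all(yrs %in% covered))
    }, by = patient_id]
    fail <- verdict$patient_id[!verdict$eligible]
    if (length(fail)) {
      excl$visits <- data.table::data.table(patient_id = fail, reason = "insufficient_annual_visits")
    }
    no_rec <- setdiff(pt$patient_id, verdict$patient_id)
    pt <- pt[patient_id %in% verdict$patient_id[verdict$eligible]]
  }
  if (length(no_rec)) {
    excl$norec <- data.table::data.table(patient_id = no_rec, reason = "no_records")
    pt <- pt[!patient_id %in% no_rec]
  }
  exclusions <- if (length(excl)) data.table::rbindlist(excl) else
    data.table::data.table(patient_id = character(), reason = character())
  list(eligible = pt[], exclusions = exclusions[])
}

#' Compute index date, mean age, and age stratum per patient
#'
#' The index date is the earliest event carrying a T2DM code; mean age is the
#' average of the patient's age at the index date and at the last visit date
#' (ages as exact fractional years, days / 365.25). Patients without any
#' T2DM-coded event are excluded with reason `no_t2dm_code`.
#'
#' @param events Event table.
#' @param patients Eligible patient table (from [apply_eligibility()]).
#' @param t2dm_code_set Character vector of codes identifying T2DM; matched
#'   exactly, or by three-character stem when `match_stem = TRUE`.
#' @param match_stem Match T2DM codes by stem (so `E11.3` counts as `E11`)?
#'   Default `FALSE`.
#' @return A list: `cohort` (`patient_id`, `sex`, `index_date`,
#'   `last_visit_date`, `mean_age`, `age_stratum`) and `exclusions`.
#' @export
compute_index_and_age <- function(events, patients, t2dm_code_set = "E11",
                                  match_stem = FALSE) {
  ev <- data.table::as.data.table(events)[patient_id %in% patients$patient_id]
  code_match <- if (match_stem) icd_stem(ev$icd10_code) %in% icd_stem(t2dm_code_set)
                else ev$icd10_code %in% t2dm_code_set
  t2 <- ev[code_match]
  idx <- if (nrow(t2)) t2[, .(index_date = min(visit_date)), by = patient_id]
         else data.table::data.table(patient_id = character(),
                                     index_date = as.Date(character()))
  last <- ev[, .(last_visit_date = max(visit_date)), by = patient_id]
  cohort <- merge(merge(patients, idx, by = "patient_id"), last, by = "patient_id")
  no_t2dm <- setdiff(patients$patient_id, idx$patient_id)
  exclusions <- data.table::data.table(
    patient_id = no_t2dm,
    reason = rep("no_t2dm_code", length(no_t2dm))
  )
  age_at <- function(d, b) as.numeric(d - b) / 365.25
  cohort[, mean_age := (age_at(index_date, birth_date) +
                          age_at(last_visit_date, birth_date)) / 2]
  cohort[, age_stratum := assign_age_band(mean_age)]
  cohort[, birth_date := NULL]
  list(cohort = cohort[], exclusions = exclusions)
}

# Granularity rule: a bare three-character code is dropped when the catalog
# also carries four-plus-character codes under the same stem with *both*
# chronic and acute flags among them (the subdivided codes are analysed
# separately in that case).
resolve_granularity <- function(catalog) {
  ct <- data.table::as.data.table(catalog)
  sub <- ct[grepl("\\.", code)]
  if (nrow(sub) == 0) return(ct)
  mixed <- sub[, .(both = any(chronic_flag) && any(!chronic_flag)), by = .(stem = icd_stem(code))]
  drop_stems <- mixed$stem[mixed$both]
  ct[!(code %in% drop_stems)]
}

#' Select the analyzable condition universe and per-patient condition sets
#'
#' Applies the multimorbidity condition rules: only diagnoses dated on or
#' after the patient's index date count; only catalog codes from ICD-10
#' chapters 1-14 are analyzable; the bare T2DM index code is excluded (its
#' subdivided complication codes, when present in the catalog, are ordinary
#' conditions); three-character codes whose stem has both chronic and acute
#' subdivided codes are replaced by those subdivisions; and only codes with
#' cohort prevalence at or above `min_prevalence` are retained. Prevalence is
#' computed on the pooled cohort (both sexes) so all strata share one
#' condition universe.
#'
#' @param events Event table.
#' @param cohort Cohort table from [compute_index_and_age()].
#' @param catalog Condition catalog.
#' @param min_prevalence Minimum cohort prevalence (fraction), default 0.01.
#' @param missing_code_action What to do with event codes absent from the
#'   catalog: `"warn"` (drop with a warning, default) or `"error"`.
#' @return A list: `universe` (retained catalog rows), `condition_sets`
#'   (`patient_id`, `code`, one row per distinct post-index condition),
#'   `prevalence` (per analyzable code), `chronic_codes` (retained chronic
#'   codes), and `multimorbid` (per-patient flag: >= 1 chronic retained
#'   condition plus >= 1 other retained condition).
#' @export
select_conditions <- function(events, cohort, catalog, min_prevalence = 0.01,
                              missing_code_action = c("warn", "error")) {
  missing_code_action <- match.arg(missing_code_action)
  ev <- data.table::as.data.table(events)
  ct <- data.table::as.data.table(catalog)
  co <- data.table::as.data.table(cohort)

  unknown <- setdiff(unique(ev$icd10_code), ct$code)
  if (length(unknown)) {
    msg <- sprintf("%d event code(s) not in catalog: %s", length(unknown),
                   paste(utils::head(unknown, 5), collapse = ", "))
    if (missing_code_action == "error") stop(msg, call. = FALSE)
    warning(paste(msg, "- dropped"))
    ev <- ev[icd10_code %in% ct$code]
  }

  ct <- resolve_granularity(ct)
  analyzable <- ct[chapter >= 1 & chapter <= 14 & !is_t2dm_index]

  ev <- merge(ev, co[, .(patient_id, index_date)], by = "patient_id")
  post <- ev[visit_date >= index_date & icd10_code %in% analyzable$code]
  sets_all <- unique(post[, .(patient_id, code = icd10_code)])

  n_cohort <- nrow(co)
  prev <- sets_all[, .(n = data.table::uniqueN(patient_id)), by = code]
  prev[, prevalence := n / n_cohort]
  keep <- prev$code[prev$prevalence >= min_prevalence]

  universe <- analyzable[code %in% keep]
  condition_sets <- sets_all[code %in% keep]
  data.table::setorder(condition_sets, patient_id, code)
  chronic_codes <- universe$code[universe$chronic_flag]

  mm <- condition_sets[, .(
    n_cond = .N,
    has_chronic = any(code %in% chronic_codes)
  ), by = patient_id]
  multimorbid <- mm[, .(patient_id, multimorbid = n_cond >= 2L & has_chronic)]

  list(universe = universe[], condition_sets = condition_sets[],
       prevalence = prev[], chronic_codes = chronic_codes,
       multimorbid = multimorbid[])
}
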