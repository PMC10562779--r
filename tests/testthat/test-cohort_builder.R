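# Cohort construction: loading/validation, the annual-visit eligibility
# rule, index date and mean age, and condition selection.

make_events <- function(...) {
  rows <- list(...)
  data.table::data.table(
    patient_id = vapply(rows, `[[`, "", 1),
    visit_date = as.Date(vapply(rows, `[[`, "", 2)),
    visit_type = vapply(rows, `[[`, "", 3),
    icd10_code = vapply(rows, `[[`, "", 4)
  )
}

make_patients <- function(ids, sex = "male", birth = "1960-06-15") {
  data.table::data.table(patient_id = ids,
                         sex = rep_len(sex, length(ids)),
                         birth_date = as.Date(rep_len(birth, length(ids))))
}

test_that("well-formed records round-trip and schema violations are caught", {
  dir <- withr::local_tempdir()
  ev <- make_events(
    list("P1", "2014-03-01", "outpatient", "I10"),
    list("P2", "2015-07-12", "inpatient", "E78"),
    list("P3", "2016-01-05", "outpatient", "K29.5"),
    list("P4", "2017-11-30", "outpatient", "E11"),
    list("P5", "2018-02-14", "inpatient", "M13")
  )
  pt <- make_patients(paste0("P", 1:5))
  ct <- data.table::data.table(code = c("I10", "E78", "K29.5", "E11", "M13"),
                               chapter = c(9L, 4L, 11L, 4L, 13L),
                               chronic_flag = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                               is_t2dm_index = c(FALSE, FALSE, FALSE, TRUE, FALSE))
  data.table::fwrite(ev, file.path(dir, "e.csv"))
  data.table::fwrite(pt, file.path(dir, "p.csv"))
  data.table::fwrite(ct, file.path(dir, "c.csv"))
  loaded <- load_records(file.path(dir, "e.csv"), file.path(dir, "p.csv"),
                         file.path(dir, "c.csv"))
  expect_equal(nrow(loaded$patients), 5L)
  expect_equal(nrow(loaded$events), 5L)
  expect_s3_class(loaded$events$visit_date, "Date")

  bad <- data.table::copy(ev)[2, visit_type := "ER"]
  data.table::fwrite(bad, file.path(dir, "bad.csv"))
  expect_error(load_records(file.path(dir, "bad.csv"), file.path(dir, "p.csv"),
                            file.path(dir, "c.csv")),
               "outpatient, inpatient")

  noev <- ev[0]
  data.table::fwrite(noev, file.path(dir, "empty.csv"))
  expect_warning(
    loaded0 <- load_records(file.path(dir, "empty.csv"), file.path(dir, "p.csv"),
                            file.path(dir, "c.csv")),
    "empty")
  expect_equal(nrow(loaded0$events), 0L)

  miss <- ev[, .(patient_id, visit_date, icd10_code)]
  data.table::fwrite(miss, file.path(dir, "miss.csv"))
  expect_error(load_records(file.path(dir, "miss.csv"), file.path(dir, "p.csv"),
                            file.path(dir, "c.csv")),
               "visit_type")
})

test_that("annual visit quota: 3 outpatient OR 1 inpatient in every spanned year", {
  # P1: 3 outpatient visits in each of 2014-2016 -> eligible
  # P2: 2 outpatient + 1 inpatient in 2015 (only year) -> eligible via
  #     the hospitalization clause
  # P3: spans 2014-2016 but 2015 has only 2 outpatient visits -> ineligible
  ev <- make_events(
    list("P1", "2014-01-10", "outpatient", "E11"), list("P1", "2014-05-10", "outpatient", "I10"),
    list("P1", "2014-09-10", "outpatient", "I10"), list("P1", "2015-01-10", "outpatient", "E11"),
    list("P1", "2015-05-10", "outpatient", "I10"), list("P1", "2015-09-10", "outpatient", "I10"),
    list("P1", "2016-01-10", "outpatient", "E11"), list("P1", "2016-05-10", "outpatient", "I10"),
    list("P1", "2016-09-10", "outpatient", "I10"),
    list("P2", "2015-02-01", "outpatient", "E11"), list("P2", "2015-03-01", "outpatient", "I10"),
    list("P2", "2015-04-01", "inpatient", "E78"),
    list("P3", "2014-01-10", "outpatient", "E11"), list("P3", "2014-02-10", "outpatient", "I10"),
    list("P3", "2014-03-10", "outpatient", "I10"), list("P3", "2015-05-10", "outpatient", "I10"),
    list("P3", "2015-06-10", "outpatient", "I10"),
    list("P3", "2016-01-10", "outpatient", "I10"), list("P3", "2016-02-10", "outpatient", "I10"),
    list("P3", "2016-03-10", "outpatient", "I10")
  )
  pt <- make_patients(c("P1", "P2", "P3"))
  res <- apply_eligibility(ev, pt)
  expect_setequal(res$eligible$patient_id, c("P1", "P2"))
  expect_equal(res$exclusions[patient_id == "P3", reason],
               "insufficient_annual_visits")
})

test_that("conflicting sex and missing demographics are excluded with reasons", {
  ev <- make_events(
    list("P1", "2015-01-01", "inpatient", "E11"),
    list("P2", "2015-01-01", "inpatient", "E11"),
    list("P3", "2015-01-01", "inpatient", "E11")
  )
  pt <- rbind(make_patients("P1", sex = "male"),
              make_patients("P1", sex = "female"),
              make_patients("P2"),
              data.table::data.table(patient_id = "P3", sex = NA_character_,
                                     birth_date = as.Date("1950-01-01")))
  res <- apply_eligibility(ev, pt)
  expect_equal(res$eligible$patient_id, "P2")
  expect_equal(res$exclusions[patient_id == "P1", reason], "conflicting_sex")
  expect_equal(res$exclusions[patient_id == "P3", reason], "missing_sex")
})

test_that("eligibility is monotone in added outpatient visits", {
  spec <- synthetic_spec(n_patients = 120, n_conditions = 12, n_clusters = 2,
                         hub_conditions = 1L, seed = 23)
  sim <- generate_synthetic_cohort(spec)
  base <- apply_eligibility(sim$events, sim$population)
  # add three extra outpatient visits (in an already-covered year) to each
  # eligible patient: nobody may become ineligible
  elig_ids <- base$eligible$patient_id
  first_dates <- sim$events[patient_id %in% elig_ids,
                            .(d = min(visit_date)), by = patient_id]
  extra <- first_dates[, .(patient_id, visit_date = d,
                           visit_type = "outpatient", icd10_code = "I10")]
  extra <- extra[rep(seq_len(.N), 3)]
  more <- apply_eligibility(rbind(sim$events, extra), sim$population)
  expect_true(all(elig_ids %in% more$eligible$patient_id))
})

test_that("index date, mean age and stratum follow the definitions", {
  # born 1964-06-01: age 50 at 2014-06-01 (index), 56 at 2020-06-01 (last)
  ev <- make_events(
    list("P1", "2014-06-01", "outpatient", "E11"),
    list("P1", "2020-06-01", "outpatient", "I10"),
    list("P2", "2015-03-20", "outpatient", "I10"),
    list("P2", "2016-08-01", "inpatient", "E11")
  )
  pt <- make_patients(c("P1", "P2"), birth = c("1964-06-01", "1970-01-01"))
  res <- compute_index_and_age(ev, pt)
  p1 <- res$cohort[patient_id == "P1"]
  expect_equal(p1$index_date, as.Date("2014-06-01"))
  expect_equal(p1$mean_age, 53.0, tolerance = 0.01)
  expect_equal(as.character(p1$age_stratum), "50-59")
  # P2's index is the earliest *T2DM* code, not the earliest visit
  expect_equal(res$cohort[patient_id == "P2", index_date], as.Date("2016-08-01"))

  # a patient with no T2DM code is excluded with a reason
  ev2 <- make_events(list("P9", "2015-01-01", "outpatient", "I10"))
  res2 <- compute_index_and_age(ev2, make_patients("P9"))
  expect_equal(nrow(res2$cohort), 0L)
  expect_equal(res2$exclusions$reason, "no_t2dm_code")
})

test_that("age strata are exhaustive, mutually exclusive and boundary-correct", {
  expect_equal(as.character(assign_age_band(c(18, 39.99, 40, 49.999, 50, 69.5, 79.99, 80, 95))),
               c("<40", "<40", "40-49", "40-49", "50-59", "60-69", "70-79", ">=80", ">=80"))
  ages <- seq(18, 100, by = 0.25)
  bands <- assign_age_band(ages)
  expect_false(anyNA(bands))
  expect_equal(levels(bands), age_band_labels())
})

test_that("condition selection applies chapter, prevalence, index-date and
           granularity rules", {
  # 200-patient cohort; C50 at 40%, N40 at 10%, A15 below 1%, O80 (chapter 15)
  # at 10%, plus a pre-index diagnosis that must not count
  n <- 200
  ids <- sprintf("P%03d", 1:n)
  ev <- data.table::rbindlist(list(
    data.table::data.table(patient_id = ids, visit_date = as.Date("2014-01-01"),
                           visit_type = "outpatient", icd10_code = "E11"),
    data.table::data.table(patient_id = ids[1:80], visit_date = as.Date("2015-01-01"),
                           visit_type = "outpatient", icd10_code = "C50"),
    data.table::data.table(patient_id = ids[1:20], visit_date = as.Date("2015-06-01"),
                           visit_type = "outpatient", icd10_code = "N40"),
    data.table::data.table(patient_id = ids[1], visit_date = as.Date("2015-06-01"),
                           visit_type = "outpatient", icd10_code = "A15"),
    data.table::data.table(patient_id = ids[1:20], visit_date = as.Date("2015-06-01"),
                           visit_type = "outpatient", icd10_code = "O80"),
    # pre-index I10 for everyone: must not enter any condition set
    data.table::data.table(patient_id = ids, visit_date = as.Date("2013-06-01"),
                           visit_type = "outpatient", icd10_code = "I10")
  ))
  pt <- make_patients(ids)
  ct <- data.table::data.table(
    code = c("E11", "C50", "N40", "A15", "O80", "I10"),
    chapter = c(4L, 2L, 14L, 1L, 15L, 9L),
    chronic_flag = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE),
    is_t2dm_index = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  cohort <- compute_index_and_age(ev, pt)$cohort
  sel <- select_conditions(ev, cohort, ct)
  expect_setequal(sel$universe$code, c("C50", "N40"))   # A15 < 1%, O80 chapter 15
  expect_false("I10" %in% sel$condition_sets$code)      # pre-index only
  expect_false("E11" %in% sel$universe$code)            # bare index code

  # idempotence: re-running on its own retained output changes nothing
  sel2 <- select_conditions(ev[icd10_code %in% c("E11", sel$universe$code)],
                            cohort, ct)
  expect_identical(sel$universe, sel2$universe)
  expect_identical(sel$condition_sets, sel2$condition_sets)
})

test_that("three-character stems with mixed chronic/acute subdivisions defer
           to their four-character codes", {
  ct <- data.table::data.table(
    code = c("K29", "K29.1", "K29.5", "M13", "M13.9", "E11"),
    chapter = c(11L, 11L, 11L, 13L, 13L, 4L),
    chronic_flag = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
    is_t2dm_index = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  resolved <- mmnet:::resolve_granularity(ct)
  # K29 has both acute (K29.1) and chronic (K29.5) children -> stem dropped
  expect_false("K29" %in% resolved$code)
  expect_true(all(c("K29.1", "K29.5") %in% resolved$code))
  # M13's children are uniformly chronic -> stem stays
  expect_true("M13" %in% resolved$code)
})
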