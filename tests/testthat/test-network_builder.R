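# Pair counting, SCI/phi/t statistics, cut-off calibration, and network
# assembly, checked against brute-force oracles and closed forms.

test_that("contingency counts match direct enumeration on small examples", {
  sets <- list(P1 = c("A", "B"), P2 = c("A", "B", "C"), P3 = "A",
               P4 = c("B", "C"), P5 = "C")
  counts <- contingency_counts(sets_to_dt(sets), c("A", "B", "C"), 5)
  expect_equal(counts$N, 5)
  marg <- setNames(counts$marginals$c, counts$marginals$code)
  expect_equal(marg, c(A = 3L, B = 3L, C = 3L))
  p <- counts$pairs
  expect_equal(p[code_i == "A" & code_j == "B", c_ij], 2L)
  expect_equal(p[code_i == "A" & code_j == "C", c_ij], 1L)
  expect_equal(p[code_i == "B" & code_j == "C", c_ij], 2L)

  single <- contingency_counts(sets_to_dt(list(P1 = "A")), c("A", "B"), 1)
  expect_equal(nrow(single$pairs), 0L)
  expect_equal(single$marginals$c, 1L)
})

test_that("contingency counts agree with the brute-force oracle, with and
           without the chronic gate", {
  codes <- sprintf("C%02d", 1:12)
  chronic <- codes[1:5]
  sets <- random_condition_sets(50, codes, mean_conditions = 3, seed = 99)
  for (gate in list(NULL, chronic)) {
    got <- contingency_counts(sets_to_dt(sets), codes, 50, chronic_codes = gate)
    want <- oracle_counts(sets, codes, 50, chronic_codes = gate)
    expect_equal(setNames(got$marginals$c, got$marginals$code), want$marginals)
    expect_equal(as.data.frame(got$pairs[, .(code_i, code_j, c_ij)]),
                 want$pairs[, c("code_i", "code_j", "c_ij")])
  }
})

test_that("SCI, phi and t reproduce hand-computed values", {
  mk <- function(ci, cj, cij, N) {
    pair_statistics(list(
      N = N,
      pairs = data.table::data.table(code_i = "A", code_j = "B",
                                     c_i = ci, c_j = cj, c_ij = cij)))
  }
  expect_equal(mk(4, 16, 2, 100)$sci, 0.25)          # 2 / sqrt(64)
  ind <- mk(10, 10, 1, 100)                          # c_ij*N = c_i*c_j
  expect_equal(ind$phi, 0)
  expect_equal(ind$t, 0)
  st <- mk(20, 30, 12, 100)
  expect_equal(st$phi, 600 / sqrt(20 * 30 * 80 * 70), tolerance = 1e-12)
  expect_equal(st$t, st$phi * sqrt(10) / sqrt(1 - st$phi^2), tolerance = 1e-12)
  expect_equal(round(st$phi, 4), 0.3273)
  expect_equal(round(st$t, 3), 1.095)
  # degenerate marginal: phi undefined, flagged not silently NaN
  deg <- mk(100, 30, 12, 100)
  expect_false(deg$valid)
  expect_equal(deg$reason, "marginal_equals_N")
  expect_true(is.na(deg$phi))
})

test_that("phi sign matches c_ij*N - c_i*c_j and SCI is symmetric in i,j", {
  set.seed(42)
  for (rep in 1:50) {
    N <- sample(20:200, 1)
    ci <- sample(1:(N - 1), 1); cj <- sample(1:(N - 1), 1)
    cij <- sample(0:min(ci, cj), 1)
    st <- pair_statistics(list(N = N, pairs = data.table::data.table(
      code_i = "A", code_j = "B", c_i = ci, c_j = cj, c_ij = cij)))
    sw <- pair_statistics(list(N = N, pairs = data.table::data.table(
      code_i = "A", code_j = "B", c_i = cj, c_j = ci, c_ij = cij)))
    expect_equal(st$sci, sw$sci)
    if (isTRUE(st$valid) && st$phi != 0) {
      expect_equal(sign(st$phi), sign(cij * N - ci * cj))
    }
    expect_equal(st$sci == 0, cij == 0)
  }
})

test_that("cut-off calibration follows the four steps and matches the oracle", {
  # three strong pairs pass both screens (a fourth weak pair keeps the mean
  # co-occurrence below them) -> e = 3, cutoff = smallest of their SCIs
  full <- pair_statistics(list(N = 1000, pairs = data.table::data.table(
    code_i = c("A", "A", "B", "D"), code_j = c("B", "C", "C", "E"),
    c_i = c(300, 300, 320, 400), c_j = c(320, 350, 350, 400),
    c_ij = c(200, 210, 250, 4))))
  res <- determine_sci_cutoff(full)
  expect_equal(res$q, 4L)
  expect_equal(res$e, 3L)
  expect_equal(res$sci_cutoff, sort(full$sci, decreasing = TRUE)[3])
  expect_setequal(res$retained_pairs$code_i, c("A", "A", "B"))

  # nothing passes the t screen -> empty network with a warning, not an error
  none <- pair_statistics(list(N = 1000, pairs = data.table::data.table(
    code_i = "A", code_j = "B", c_i = 100, c_j = 100, c_ij = 10)))
  expect_warning(res0 <- determine_sci_cutoff(none), "no pair passes")
  expect_equal(res0$e, 0L)
  expect_equal(nrow(res0$retained_pairs), 0L)

  # 200 random pairs: identical to the literal brute-force implementation
  set.seed(7)
  N <- 5000
  dt <- data.table::data.table(
    code_i = sprintf("A%03d", 1:200), code_j = sprintf("B%03d", 1:200),
    c_i = sample(50:1500, 200, TRUE), c_j = sample(50:1500, 200, TRUE))
  dt[, c_ij := pmin(c_i, c_j)]
  dt[, c_ij := sapply(seq_len(.N), function(i) sample(0:c_ij[i], 1))]
  st <- pair_statistics(list(N = N, pairs = dt[c_ij > 0]))
  got <- determine_sci_cutoff(st)
  want <- oracle_cutoff(as.data.frame(st))
  expect_equal(got$q, want$q)
  expect_equal(got$e, want$e)
  expect_equal(got$sci_cutoff, want$sci_cutoff, tolerance = 1e-15)
  expect_equal(as.data.frame(got$retained_pairs[, .(code_i, code_j)]),
               want$retained[, c("code_i", "code_j")])
  # cutoff-count sandwich: #\{sci > cutoff\} <= e <= #retained
  expect_lte(sum(st$sci > got$sci_cutoff), got$e)
  expect_gte(nrow(got$retained_pairs), got$e)
})

test_that("built networks preserve weights and satisfy the graph invariants", {
  cut <- list(retained_pairs = data.table::data.table(
    code_i = c("A", "B"), code_j = c("B", "C"), sci = c(0.5, 0.4)))
  g <- build_network(cut, "toy")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  expect_setequal(igraph::E(g)$weight, c(0.5, 0.4))
  expect_equal(igraph::graph_attr(g, "stratum"), "toy")
  expect_false(igraph::any_loop(g))
  expect_false(igraph::any_multiple(g))
  expect_true(all(igraph::degree(g) >= 1))
  expect_true(all(igraph::E(g)$weight > 0 & igraph::E(g)$weight <= 1))

  g0 <- build_network(list(retained_pairs = NULL))
  expect_equal(igraph::vcount(g0), 0)
})

test_that("duplicating every patient leaves SCI unchanged while the
           significance screen shifts", {
  codes <- sprintf("C%02d", 1:10)
  sets <- random_condition_sets(80, codes, mean_conditions = 4, seed = 5)
  st1 <- pair_statistics(contingency_counts(sets_to_dt(sets), codes, 80))
  dup <- c(sets, setNames(sets, sprintf("Q%04d", seq_along(sets))))
  st2 <- pair_statistics(contingency_counts(sets_to_dt(dup), codes, 160))
  m <- merge(st1, st2, by = c("code_i", "code_j"))
  expect_gt(nrow(m), 10)
  expect_equal(m$sci.x, m$sci.y, tolerance = 1e-12)
  # phi, a correlation, is also invariant under exact duplication; the
  # sample-size dependence of the phi-based screen enters through t, whose
  # degrees of freedom double
  expect_equal(m$phi.x, m$phi.y, tolerance = 1e-12)
  moved <- m[is.finite(t.x) & t.x != 0]
  expect_true(all(abs(moved$t.x - moved$t.y) > 1e-12))
})

test_that("stratified networks equal the single-stratum pipeline on each subset", {
  spec <- synthetic_spec(n_patients = 1200, n_conditions = 30, seed = 77)
  sim <- generate_synthetic_cohort(spec)
  elig <- apply_eligibility(sim$events, sim$population)
  cohort <- compute_index_and_age(sim$events, elig$eligible)$cohort
  sel <- select_conditions(sim$events, cohort, sim$catalog)
  nets <- suppressWarnings(build_stratified_networks(
    cohort, sel$condition_sets, sel$universe$code,
    chronic_codes = sel$chronic_codes, min_patients = 20))
  expect_true(any(grepl("^male:", names(nets))))
  expect_true(any(grepl("^female:", names(nets))))

  lbl <- grep(":global$", names(nets), value = TRUE)[1]
  s <- sub(":global$", "", lbl)
  pid <- cohort$patient_id[cohort$sex == s]
  direct <- suppressWarnings(build_stratum_network(
    sel$condition_sets[patient_id %in% pid], sel$universe$code, length(pid),
    chronic_codes = sel$chronic_codes, stratum_label = lbl))
  expect_identical(
    igraph::as_data_frame(nets[[lbl]]$network, what = "edges"),
    igraph::as_data_frame(direct$network, what = "edges"))

  # tiny strata are skipped with a warning, not built
  small <- cohort[1:5]
  w <- capture_warnings(
    build_stratified_networks(small, sel$condition_sets, sel$universe$code,
                              min_patients = 30))
  expect_true(any(grepl("skipped", w)))
})
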