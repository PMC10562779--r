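# Pairwise contingency counts, Salton-cosine / phi / t statistics, the
# phi-calibrated SCI cut-off, and assembly of weighted multimorbidity
# networks (global, sex x age stratum, yearly snapshots).

#' Exact contingency counts for all disease pairs in one stratum
#'
#' Counts, for every condition, the number of patients carrying it (`c_i`),
#' and for every unordered pair with at least one co-occurrence, the number
#' of patients carrying both (`c_ij`). When `chronic_codes` is supplied, pair
#' counts are restricted to patients with at least one chronic retained
#' condition (the multimorbidity definition: one chronic condition plus at
#' least one other); marginal counts always use all patients.
#'
#' @param condition_sets `data.table` (`patient_id`, `code`), one row per
#'   distinct patient-condition.
#' @param condition_universe Character vector of analyzable codes.
#' @param n_patients Total patient count `N` of the stratum (patients without
#'   any retained condition still count toward `N`).
#' @param chronic_codes Optional character vector of chronic codes gating
#'   pair counting; `NULL` (default) counts pairs over all patients.
#' @return A list: `N`, `marginals` (`code`, `c`), `pairs` (`code_i`,
#'   `code_j`, `c_i`, `c_j`, `c_ij`; lexicographic `code_i < code_j`, only
#'   pairs with `c_ij > 0`).
#' @export
contingency_counts <- function(condition_sets, condition_universe, n_patients,
                               chronic_codes = NULL) {
  cs <- data.table::as.data.table(condition_sets)
  cs <- unique(cs[code %in% condition_universe, .(patient_id, code)])
  empty <- list(
    N = n_patients,
    marginals = data.table::data.table(code = character(), c = integer()),
    pairs = data.table::data.table(code_i = character(), code_j = character(),
                                   c_i = integer(), c_j = integer(), c_ij = integer())
  )
  if (nrow(cs) == 0) {
    warning("empty stratum: no conditions to count")
    return(empty)
  }
  codes <- sort(unique(cs$code))
  pids <- sort(unique(cs$patient_id))
  X <- Matrix::sparseMatrix(
    i = match(cs$patient_id, pids),
    j = match(cs$code, codes),
    x = 1,
    dims = c(length(pids), length(codes))
  )
  marg <- data.table::data.table(code = codes, c = as.integer(Matrix::colSums(X)))

  if (!is.null(chronic_codes)) {
    eligible <- cs[, .(ok = any(code %in% chronic_codes)), by = patient_id]
    rows <- match(eligible$patient_id[eligible$ok], pids)
    Xp <- X[rows, , drop = FALSE]
  } else {
    Xp <- X
  }
  CP <- as(Matrix::crossprod(Xp), "TsparseMatrix")
  keep <- CP@i < CP@j  # strict upper triangle: unordered pairs, no self-pairs
  pairs <- data.table::data.table(
    code_i = codes[CP@i[keep] + 1L],
    code_j = codes[CP@j[keep] + 1L],
    c_ij = as.integer(CP@x[keep])
  )
  pairs <- pairs[c_ij > 0L]
  pairs[, c_i := marg$c[match(code_i, marg$code)]]
  pairs[, c_j := marg$c[match(code_j, marg$code)]]
  data.table::setcolorder(pairs, c("code_i", "code_j", "c_i", "c_j", "c_ij"))
  data.table::setorder(pairs, code_i, code_j)
  list(N = n_patients, marginals = marg[], pairs = pairs[])
}

#' Salton cosine index, phi coefficient, and t statistic per disease pair
#'
#' For each pair: `sci = c_ij / sqrt(c_i * c_j)`;
#' `phi = (c_ij*N - c_i*c_j) / sqrt(c_i*c_j*(N-c_i)*(N-c_j))`;
#' `t = phi * sqrt(c_ij - 2) / sqrt(1 - phi^2)`.
#' The t statistic is set to 0 when `c_ij <= 2` (undefined degrees of
#' freedom; such pairs fail the significance screen) and to signed infinity
#' when `|phi| = 1`. Pairs with `c_i = N` or `c_j = N` have an undefined phi
#' denominator: they are flagged invalid with a reason and take no part in
#' the cut-off calibration.
#'
#' @param counts Result of [contingency_counts()].
#' @return `data.table` with columns `code_i`, `code_j`, `c_i`, `c_j`,
#'   `c_ij`, `N`, `sci`, `phi`, `t`, `valid`, `reason`.
#' @export
pair_statistics <- function(counts) {
  st <- data.table::copy(counts$pairs)
  N <- counts$N
  if (nrow(st) == 0) {
    st[, c("N", "sci", "phi", "t", "valid", "reason") :=
         list(integer(), numeric(), numeric(), numeric(), logical(), character())]
    return(st[])
  }
  st[, N := as.integer(N)]
  st[, sci := c_ij / sqrt(as.numeric(c_i) * as.numeric(c_j))]
  st[, valid := c_i < N & c_j < N]
  st[, reason := data.table::fifelse(valid, NA_character_, "marginal_equals_N")]
  st[, phi := NA_real_]
  st[(valid), phi := (c_ij * as.numeric(N) - as.numeric(c_i) * as.numeric(c_j)) /
       sqrt(as.numeric(c_i) * as.numeric(c_j) *
              as.numeric(N - c_i) * as.numeric(N - c_j))]
  st[, t := NA_real_]
  st[(valid), t := data.table::fcase(
    c_ij <= 2L, 0,
    abs(phi) >= 1, sign(phi) * Inf,
    default = NA_real_
  )]
  fin <- st$valid & st$c_ij > 2L & abs(st$phi) < 1
  st[fin, t := phi * sqrt(c_ij - 2) / sqrt(1 - phi^2)]
  st[]
}

#' Calibrate the SCI cut-off against the phi significance screen
#'
#' The four-step calibration: (1) compute SCI and phi for all pairs; (2)
#' `q` = number of pairs with `c_ij > 0`; (3) `e` = number of pairs passing
#' both screens, `t > t_critical` (two-sided p < 0.01 by default) and
#' `c_ij > sum(c_ij)/q`; (4) the SCI cut-off is the `e`-th largest SCI among
#' the `q` pairs, and the retained edge set is every pair with
#' `sci >= cutoff` (ties included). The principle: the SCI network keeps
#' exactly as many edges as there are significantly, positively correlated
#' pairs under phi.
#'
#' @param stats Pair statistics from [pair_statistics()].
#' @param t_critical Critical value for the t screen (default 2.58, the
#'   two-sided normal value at p = 0.01).
#' @return A list: `q`, `e`, `mean_cij`, `sci_cutoff`, `retained_pairs`
#'   (rows of `stats`). `e = 0` yields an empty retained set with a warning.
#' @export
determine_sci_cutoff <- function(stats, t_critical = 2.58) {
  st <- data.table::as.data.table(stats)
  st <- st[valid == TRUE & c_ij > 0L]
  q <- nrow(st)
  if (q == 0) {
    warning("no co-occurring disease pairs: empty network")
    return(list(q = 0L, e = 0L, mean_cij = NA_real_, sci_cutoff = Inf,
                retained_pairs = st))
  }
  mean_cij <- sum(st$c_ij) / q
  e <- sum(st$t > t_critical & st$c_ij > mean_cij)
  if (e == 0) {
    warning("no pair passes the significance screen: empty network")
    return(list(q = q, e = 0L, mean_cij = mean_cij, sci_cutoff = Inf,
                retained_pairs = st[0]))
  }
  sci_sorted <- sort(st$sci, decreasing = TRUE)
  sci_cutoff <- sci_sorted[e]
  retained <- st[sci >= sci_cutoff]
  data.table::setorder(retained, code_i, code_j)
  list(q = q, e = as.integer(e), mean_cij = mean_cij,
       sci_cutoff = sci_cutoff, retained_pairs = retained[])
}

#' Build a multimorbidity network from retained pairs
#'
#' Undirected simple graph; nodes are the endpoints of retained edges (so
#' every node has degree >= 1), edge weights are the SCI values.
#'
#' @param cutoff Result of [determine_sci_cutoff()].
#' @param stratum_label Label stored as the graph's `stratum` attribute.
#' @return An `igraph` graph with edge attribute `weight` (= SCI).
#' @export
build_network <- function(cutoff, stratum_label = "global") {
  rp <- cutoff$retained_pairs
  if (is.null(rp) || nrow(rp) == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      rp[, .(from = code_i, to = code_j, weight = sci)],
      directed = FALSE
    )
  }
  g <- igraph::set_graph_attr(g, "stratum", stratum_label)
  g
}

# Full single-stratum pipeline: counts -> stats -> cutoff -> network.
build_stratum_network <- function(condition_sets, condition_universe, n_patients,
                                  chronic_codes = NULL, t_critical = 2.58,
                                  stratum_label = "global") {
  counts <- contingency_counts(condition_sets, condition_universe, n_patients,
                               chronic_codes = chronic_codes)
  stats <- pair_statistics(counts)
  cutoff <- determine_sci_cutoff(stats, t_critical = t_critical)
  list(network = build_network(cutoff, stratum_label), cutoff = cutoff,
       stats = stats, N = n_patients, label = stratum_label)
}

#' Build global-per-sex and sex-by-age-stratum networks
#'
#' One network per non-empty (sex x age band) stratum — up to twelve — plus
#' one global network per sex. Counts, statistics and the SCI cut-off are
#' computed *within* each stratum (stratum-internal `N`).
#'
#' @param cohort Cohort table (`patient_id`, `sex`, `age_stratum`).
#' @param condition_sets Per-patient condition sets (`patient_id`, `code`).
#' @param condition_universe Character vector of analyzable codes (shared
#'   across strata).
#' @param chronic_codes Optional chronic codes gating pair counts.
#' @param t_critical Significance screen critical value.
#' @param min_patients Strata with fewer patients are skipped with a warning.
#' @return Named list of stratum results (see [build_stratum_network()]);
#'   names like `"male:global"`, `"female:50-59"`.
#' @export
build_stratified_networks <- function(cohort, condition_sets, condition_universe,
                                      chronic_codes = NULL, t_critical = 2.58,
                                      min_patients = 30) {
  co <- data.table::as.data.table(cohort)
  cs <- data.table::as.data.table(condition_sets)
  out <- list()
  for (s in c("male", "female")) {
    strata <- c("global", age_band_labels())
    for (band in strata) {
      pid <- if (band == "global") co$patient_id[co$sex == s]
             else co$patient_id[co$sex == s & co$age_stratum == band]
      label <- paste(s, band, sep = ":")
      if (length(pid) < min_patients) {
        warning(sprintf("stratum %s has %d patient(s) (< %d): skipped",
                        label, length(pid), min_patients))
        next
      }
      res <- suppressWarnings(build_stratum_network(
        cs[patient_id %in% pid], condition_universe, length(pid),
        chronic_codes = chronic_codes, t_critical = t_critical,
        stratum_label = label
      ))
      out[[label]] <- res
    }
  }
  out
}
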