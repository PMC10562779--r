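# The three categories of crucial diseases — hub (PageRank), root
# (eigenvector centrality within Louvain communities), burst (degree growth
# across adjacent age strata) — their intersection (core diseases), and
# temporal degree trends on cumulative yearly networks.

# Deterministic ordering: by score (desc), then weighted degree (desc), then
# code (asc). Scores are rounded to 10 significant digits first so that
# numerically near-tied values (e.g. symmetric graphs) break ties by the
# stated rule rather than by floating-point noise. Returns the permutation.
.rank_nodes <- function(score, wdeg, code) {
  order(-signif(score, 10), -signif(wdeg, 10), code)
}

#' Identify hub diseases by PageRank
#'
#' PageRank on the SCI-weighted undirected graph (each edge acting as two
#' directed arcs with transition probability proportional to its weight).
#' The top `k` nodes are the hub diseases. Ties are broken by weighted
#' degree, then code, and flagged.
#'
#' @param network An `igraph` graph with `weight` edge attribute.
#' @param k Number of hubs (default 10).
#' @param damping PageRank damping factor (default 0.85).
#' @return `data.table` (`code`, `pagerank`, `rank`, `tied`), `k` rows (or
#'   all nodes, with a warning, when `k` exceeds the node count).
#' @export
identify_hub_diseases <- function(network, k = 10, damping = 0.85) {
  n <- igraph::vcount(network)
  if (n == 0) stop("cannot identify hubs in an empty network", call. = FALSE)
  if (k > n) {
    warning(sprintf("k = %d exceeds node count %d: returning all nodes", k, n))
    k <- n
  }
  pr <- igraph::page_rank(network, damping = damping,
                          weights = igraph::E(network)$weight)$vector
  wdeg <- igraph::strength(network)
  code <- igraph::V(network)$name
  ord <- .rank_nodes(pr, wdeg, code)
  top <- ord[seq_len(k)]
  # a tie is flagged when the k-th and (k+1)-th scores coincide, or scores
  # repeat inside the top-k
  boundary_tie <- k < n && isTRUE(all.equal(pr[ord[k]], pr[ord[k + 1]], tolerance = 1e-12))
  dt <- data.table::data.table(
    code = code[top],
    pagerank = as.numeric(pr[top]),
    rank = seq_len(k),
    tied = duplicated(signif(pr[top], 12)) | c(rep(FALSE, k - 1), boundary_tie)
  )
  dt[]
}

#' Detect communities with the Louvain algorithm
#'
#' Weighted-modularity Louvain, best partition over `n_restarts` restarts
#' with a deterministic seed sequence derived from `seed`.
#'
#' @param network An `igraph` graph with `weight` edge attribute.
#' @param seed Master seed for the restart sequence.
#' @param n_restarts Number of restarts (default 20).
#' @param resolution Modularity resolution parameter (default 1).
#' @return A list: `membership` (named integer vector), `modularity`,
#'   `n_communities`, `sizes`.
#' @export
detect_communities <- function(network, seed = 1L, n_restarts = 20, resolution = 1) {
  if (igraph::vcount(network) == 0) stop("cannot partition an empty network", call. = FALSE)
  best <- NULL
  best_mod <- -Inf
  for (r in seq_len(n_restarts)) {
    set.seed(derive_seed(seed, 100L + r))
    cl <- igraph::cluster_louvain(network, weights = igraph::E(network)$weight,
                                  resolution = resolution)
    mod <- igraph::modularity(cl)
    if (mod > best_mod) {
      best_mod <- mod
      best <- cl
    }
  }
  membership <- stats::setNames(as.integer(igraph::membership(best)),
                                igraph::V(network)$name)
  list(membership = membership, modularity = best_mod,
       n_communities = length(unique(membership)),
       sizes = table(membership))
}

#' Identify the root disease of each community
#'
#' Eigenvector centrality computed on each community's weighted induced
#' subgraph; the maximising node is the community's root. Single-node
#' communities have that node as root by convention (flagged); exact ties go
#' to the node with higher weighted degree, then lexicographically smallest
#' code (flagged).
#'
#' @param communities Result of [detect_communities()].
#' @param network The graph the partition was computed on.
#' @return `data.table` (`community`, `root`, `eigen_centrality`,
#'   `n_members`, `flagged`).
#' @export
identify_root_diseases <- function(communities, network) {
  membership <- communities$membership
  out <- lapply(sort(unique(membership)), function(cid) {
    members <- names(membership)[membership == cid]
    sub <- igraph::induced_subgraph(network, members)
    if (length(members) == 1L) {
      return(data.table::data.table(community = cid, root = members,
                                    eigen_centrality = NA_real_,
                                    n_members = 1L, flagged = TRUE))
    }
    ec <- igraph::eigen_centrality(sub, weights = igraph::E(sub)$weight)$vector
    wdeg <- igraph::strength(sub)
    code <- igraph::V(sub)$name
    ord <- .rank_nodes(ec, wdeg, code)
    tie <- length(ord) > 1 &&
      signif(ec[ord[1]], 10) == signif(ec[ord[2]], 10)
    data.table::data.table(community = cid, root = code[ord[1]],
                           eigen_centrality = as.numeric(ec[ord[1]]),
                           n_members = length(members), flagged = tie)
  })
  data.table::rbindlist(out)[]
}

#' Degree trajectories and burst diseases across age strata
#'
#' For each node appearing in any of a sex's age-stratified networks, its
#' degree trajectory across the six age bands (0 when absent from a band's
#' network). A burst disease shows degree growth >= `threshold` between
#' *adjacent* bands (inclusive boundary).
#'
#' @param band_networks Named list of `igraph` graphs; names must be age
#'   band labels (missing bands count as degree 0 for all nodes).
#' @param threshold Minimum degree growth (default 6).
#' @return A list: `trajectories` (`data.table`, code x band degrees) and
#'   `bursts` (`code`, `from_band`, `to_band`, `degree_before`,
#'   `degree_after`, `growth`).
#' @export
identify_burst_diseases <- function(band_networks, threshold = 6) {
  bands <- age_band_labels()
  present <- intersect(bands, names(band_networks))
  if (length(present) < 2L) {
    warning("fewer than 2 non-empty age bands: no burst analysis possible")
  }
  codes <- sort(unique(unlist(lapply(band_networks[present], function(g) {
    igraph::V(g)$name
  }))))
  traj <- data.table::data.table(code = codes)
  for (b in bands) {
    if (b %in% present) {
      g <- band_networks[[b]]
      d <- stats::setNames(as.integer(igraph::degree(g)), igraph::V(g)$name)
      traj[[b]] <- ifelse(codes %in% names(d), d[codes], 0L)
    } else {
      traj[[b]] <- rep(0L, length(codes))
    }
  }
  bursts <- list()
  for (i in seq_len(length(bands) - 1L)) {
    growth <- traj[[bands[i + 1L]]] - traj[[bands[i]]]
    hit <- which(growth >= threshold)
    if (length(hit)) {
      bursts[[length(bursts) + 1L]] <- data.table::data.table(
        code = traj$code[hit],
        from_band = bands[i], to_band = bands[i + 1L],
        degree_before = traj[[bands[i]]][hit],
        degree_after = traj[[bands[i + 1L]]][hit],
        growth = growth[hit]
      )
    }
  }
  bursts <- if (length(bursts)) data.table::rbindlist(bursts) else
    data.table::data.table(code = character(), from_band = character(),
                           to_band = character(), degree_before = integer(),
                           degree_after = integer(), growth = integer())
  list(trajectories = traj[], bursts = bursts[])
}

#' Core diseases: the intersection of hub, root and burst sets
#'
#' @param hubs Character vector (or hub table) of hub disease codes.
#' @param roots Character vector (or root table) of root disease codes.
#' @param bursts Character vector (or burst table) of burst disease codes.
#' @return Sorted character vector of core disease codes.
#' @export
identify_core_diseases <- function(hubs, roots, bursts) {
  get_codes <- function(x, col) {
    if (is.character(x)) x else unique(x[[col]])
  }
  sort(Reduce(intersect, list(get_codes(hubs, "code"),
                              get_codes(roots, "root"),
                              get_codes(bursts, "code"))))
}

#' Full crucial-disease report for one sex
#'
#' Hubs and communities/roots are identified on the sex's global network;
#' bursts on its age-stratified networks; core diseases are the three-way
#' intersection.
#'
#' @param global_network The sex's global `igraph` network.
#' @param band_networks Named list of the sex's age-band networks.
#' @param k Hub count (default 10).
#' @param damping PageRank damping.
#' @param burst_threshold Degree-growth threshold (default 6).
#' @param seed,n_restarts Louvain reproducibility controls.
#' @return A list: `hubs`, `communities`, `roots`, `bursts` (with
#'   trajectories), `cores`.
#' @export
crucial_disease_report <- function(global_network, band_networks, k = 10,
                                   damping = 0.85, burst_threshold = 6,
                                   seed = 1L, n_restarts = 20) {
  hubs <- identify_hub_diseases(global_network, k = k, damping = damping)
  comm <- detect_communities(global_network, seed = seed, n_restarts = n_restarts)
  roots <- identify_root_diseases(comm, global_network)
  burst <- identify_burst_diseases(band_networks, threshold = burst_threshold)
  cores <- identify_core_diseases(hubs, roots, burst$bursts)
  list(hubs = hubs, communities = comm, roots = roots,
       bursts = burst, cores = cores)
}

#' Temporal degree trends on cumulative yearly networks
#'
#' Restricts to the continuity cohort — patients whose index date falls in
#' the first study year and whose records satisfy the annual visit quota in
#' every study year — then, for each year from `baseline_year` to
#' `end_year`, builds a network from all post-index diagnoses dated up to
#' the end of that year and reports the degree of each disease. Seven
#' networks at the defaults (baseline 2015, end 2021).
#'
#' @param events Event table.
#' @param cohort Cohort table (`patient_id`, `index_date` at least).
#' @param condition_sets Per-patient condition sets *with dates not applied*:
#'   pass `NULL` to derive sets from `events` (the usual route).
#' @param condition_universe Analyzable codes.
#' @param chronic_codes Optional chronic codes gating pair counts.
#' @param first_year First study year (default 2013).
#' @param baseline_year First network year (default 2015).
#' @param end_year Last network year (default 2021).
#' @param t_critical Significance screen critical value.
#' @param disease_set Codes whose degrees to report (default: all universe
#'   codes; absent diseases report degree 0).
#' @return A list: `networks` (named by year) and `degree_table`
#'   (`data.table`, `code` x year columns).
#' @export
temporal_degree_trends <- function(events, cohort, condition_sets = NULL,
                                   condition_universe, chronic_codes = NULL,
                                   first_year = 2013, baseline_year = 2015,
                                   end_year = 2021, t_critical = 2.58,
                                   disease_set = NULL) {
  stopifnot(first_year <= baseline_year, baseline_year <= end_year)
  ev <- data.table::as.data.table(events)
  co <- data.table::as.data.table(cohort)

  ev[, year := data.table::year(visit_date)]
  idx_year <- co[, .(patient_id, index_year = data.table::year(index_date))]
  start_ok <- idx_year$patient_id[idx_year$index_year == first_year]

  per_year <- ev[patient_id %in% start_ok,
                 .(n_out = sum(visit_type == "outpatient"),
                   n_inp = sum(visit_type == "inpatient")),
                 by = .(patient_id, year)]
  continuity <- per_year[year >= first_year & year <= end_year,
                         .(ok = all(seq(first_year, end_year) %in%
                                      year[n_out >= 3L | n_inp >= 1L])),
                         by = patient_id]
  keep <- continuity$patient_id[continuity$ok]
  if (length(keep) == 0) {
    warning("continuity cohort is empty: no temporal networks built")
    return(list(networks = list(), degree_table = data.table::data.table()))
  }
  co_keep <- co[patient_id %in% keep]
  ev_keep <- merge(ev[patient_id %in% keep],
                   co_keep[, .(patient_id, index_date)], by = "patient_id")
  ev_keep <- ev_keep[visit_date >= index_date & icd10_code %in% condition_universe]

  if (is.null(disease_set)) disease_set <- sort(condition_universe)
  networks <- list()
  deg <- data.table::data.table(code = disease_set)
  for (y in seq(baseline_year, end_year)) {
    sets_y <- unique(ev_keep[year <= y, .(patient_id, code = icd10_code)])
    res <- suppressWarnings(build_stratum_network(
      sets_y, condition_universe, length(keep),
      chronic_codes = chronic_codes, t_critical = t_critical,
      stratum_label = sprintf("year:%d", y)))
    networks[[as.character(y)]] <- res$network
    d <- stats::setNames(as.integer(igraph::degree(res$network)),
                         igraph::V(res$network)$name)
    deg[[as.character(y)]] <- ifelse(deg$code %in% names(d), d[deg$code], 0L)
  }
  list(networks = networks, degree_table = deg[])
}
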