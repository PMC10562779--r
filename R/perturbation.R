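# Perturbation analyses: single-node removal with network-metric deltas, and
# random edge deletion with top-k PageRank stability.

#' Impact of removing crucial-disease nodes, one at a time
#'
#' For each code independently (the network is restored between removals):
#' delete the node and its incident edges, drop nodes left isolated by the
#' removal (network nodes have degree >= 1 by construction), recompute the
#' structural summary, and report signed percent changes,
#' `100 * (after - before) / before`.
#'
#' @param network An `igraph` graph.
#' @param codes_to_remove Character vector of node codes.
#' @return `data.table` with one row per code: before/after summary fields,
#'   `n_isolated_dropped`, and `pct_change_*` columns for edges, density,
#'   average degree, average weighted degree, and (normalized) average
#'   harmonic centrality. Codes absent from the network yield an error row
#'   (`error = TRUE`) and the analysis continues.
#' @export
node_removal_analysis <- function(network, codes_to_remove) {
  before <- summarize_network(network)
  pct <- function(a, b) if (is.na(b) || b == 0) NA_real_ else 100 * (a - b) / b
  rows <- lapply(codes_to_remove, function(code) {
    base <- data.table::data.table(removed_code = code, error = FALSE)
    if (!code %in% igraph::V(network)$name) {
      base$error <- TRUE
      return(base)
    }
    g2 <- igraph::delete_vertices(network, code)
    iso <- which(igraph::degree(g2) == 0)
    n_iso <- length(iso)
    if (n_iso > 0) g2 <- igraph::delete_vertices(g2, iso)
    after <- summarize_network(g2)
    cbind(base, data.table::data.table(
      n_nodes_before = before$n_nodes, n_nodes_after = after$n_nodes,
      n_edges_before = before$n_edges, n_edges_after = after$n_edges,
      n_isolated_dropped = n_iso,
      pct_change_edges = pct(after$n_edges, before$n_edges),
      pct_change_density = pct(after$density, before$density),
      pct_change_avg_degree = pct(after$avg_degree, before$avg_degree),
      pct_change_avg_weighted_degree = pct(after$avg_weighted_degree,
                                           before$avg_weighted_degree),
      pct_change_avg_harmonic = pct(after$avg_harmonic, before$avg_harmonic)
    ))
  })
  data.table::rbindlist(rows, fill = TRUE)[]
}

#' Robustness of hub identification under random edge deletion
#'
#' For each removal level and replicate: delete `round(level * n_edges)`
#' edges sampled uniformly without replacement (each replicate's seed derived
#' deterministically from the master seed), recompute the top-k PageRank
#' nodes, and report the overlap with the unperturbed top-k. Levels whose
#' removal count rounds to zero are skipped with a warning (level 0 is the
#' identity perturbation and reports overlap k).
#'
#' @param network An `igraph` graph.
#' @param levels Fractions of edges to remove (default 1%, 3%, 5%).
#' @param reps Replicates per level (default 3).
#' @param k Size of the PageRank top list (default 10).
#' @param seed Master seed.
#' @param damping PageRank damping factor.
#' @return `data.table` (`level`, `rep`, `seed`, `n_removed`,
#'   `overlap_count`, `top_before`, `top_after`; the code lists as
#'   comma-joined strings).
#' @export
edge_removal_analysis <- function(network, levels = c(0.01, 0.03, 0.05),
                                  reps = 3, k = 10, seed = 1L, damping = 0.85) {
  m <- igraph::ecount(network)
  if (m == 0) stop("cannot perturb a network with no edges", call. = FALSE)
  top_before <- identify_hub_diseases(network, k = k, damping = damping)$code
  k_eff <- length(top_before)
  rows <- list()
  for (li in seq_along(levels)) {
    level <- levels[li]
    n_rm <- round(level * m)
    if (level > 0 && n_rm == 0) {
      warning(sprintf("level %.3f removes 0 of %d edges after rounding: skipped",
                      level, m))
      next
    }
    for (r in seq_len(reps)) {
      rep_seed <- derive_seed(seed, 1000L * li + r)
      if (n_rm > 0) {
        set.seed(rep_seed)
        drop <- sample.int(m, n_rm)
        g2 <- igraph::delete_edges(network, drop)
        # removal may isolate nodes; they stay for PageRank (uniform teleport)
      } else {
        g2 <- network
      }
      top_after <- suppressWarnings(
        identify_hub_diseases(g2, k = k, damping = damping)$code)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        level = level, rep = r, seed = rep_seed, n_removed = n_rm,
        overlap_count = length(intersect(top_before, top_after)),
        top_before = paste(top_before, collapse = ","),
        top_after = paste(top_after, collapse = ",")
      )
    }
  }
  if (!length(rows)) {
    return(data.table::data.table(level = numeric(), rep = integer(),
                                  seed = integer(), n_removed = integer(),
                                  overlap_count = integer(),
                                  top_before = character(), top_after = character()))
  }
  data.table::rbindlist(rows)[]
}
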