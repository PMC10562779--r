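# Structural metrics of multimorbidity networks: degree, weighted degree,
# density, closeness and harmonic centrality, plus network-level summaries.
#
# Distances are unweighted hop counts throughout: the SCI is a similarity,
# not a cost, and no weight-to-distance transform is part of the model.

#' Degree and weighted degree per node
#'
#' @param network An `igraph` graph with edge attribute `weight` (SCI).
#' @return `data.table` (`code`, `degree`, `weighted_degree`), sorted by
#'   code.
#' @export
compute_degrees <- function(network) {
  if (igraph::vcount(network) == 0) {
    return(data.table::data.table(code = character(), degree = integer(),
                                  weighted_degree = numeric()))
  }
  dt <- data.table::data.table(
    code = igraph::V(network)$name,
    degree = as.integer(igraph::degree(network)),
    weighted_degree = igraph::strength(network)
  )
  data.table::setorder(dt, code)
  dt[]
}

#' Harmonic centrality per node
#'
#' For node v, the sum over all other nodes u of 1/d(u, v), with unreachable
#' pairs contributing 0 — well defined on disconnected graphs, which is why
#' it replaces closeness for the age-stratified networks. Distances are hop
#' counts.
#'
#' @param network An `igraph` graph.
#' @param normalized Divide by (n - 1) so values are comparable across
#'   networks of different size? Default `FALSE`.
#' @return Named numeric vector (names = node codes).
#' @export
compute_harmonic_centrality <- function(network, normalized = FALSE) {
  n <- igraph::vcount(network)
  if (n == 0) return(stats::setNames(numeric(0), character(0)))
  h <- igraph::harmonic_centrality(network, weights = NA, normalized = FALSE)
  if (normalized && n > 1) h <- h / (n - 1)
  stats::setNames(as.numeric(h), igraph::V(network)$name)
}

#' Network-level structural summary
#'
#' Density, average degree, average weighted degree, average closeness
#' (computed within the largest connected component when the graph is
#' disconnected, with a flag), and average harmonic centrality (raw and
#' normalized by n - 1, averaged over all nodes).
#'
#' @param network An `igraph` graph.
#' @return A list: `n_nodes`, `n_edges`, `density` (`NA` when n < 2),
#'   `avg_degree`, `avg_weighted_degree`, `avg_closeness`, `avg_harmonic_raw`,
#'   `avg_harmonic` (normalized), `connected`, `n_components`.
#' @export
summarize_network <- function(network) {
  n <- igraph::vcount(network)
  m <- igraph::ecount(network)
  if (n == 0) {
    return(list(n_nodes = 0L, n_edges = 0L, density = NA_real_,
                avg_degree = NA_real_, avg_weighted_degree = NA_real_,
                avg_closeness = NA_real_, avg_harmonic_raw = NA_real_,
                avg_harmonic = NA_real_, connected = NA, n_components = 0L))
  }
  comp <- igraph::components(network)
  density <- if (n >= 2) 2 * m / (n * (n - 1)) else NA_real_
  h_raw <- compute_harmonic_centrality(network, normalized = FALSE)
  h_norm <- if (n > 1) h_raw / (n - 1) else h_raw
  giant <- igraph::induced_subgraph(
    network, which(comp$membership == which.max(comp$csize)))
  avg_closeness <- if (igraph::vcount(giant) >= 2) {
    mean(igraph::closeness(giant, weights = NA, normalized = TRUE))
  } else NA_real_
  list(
    n_nodes = n, n_edges = m, density = density,
    avg_degree = 2 * m / n,
    avg_weighted_degree = mean(igraph::strength(network)),
    avg_closeness = avg_closeness,
    avg_harmonic_raw = mean(h_raw),
    avg_harmonic = mean(h_norm),
    connected = comp$no == 1L,
    n_components = comp$no
  )
}
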