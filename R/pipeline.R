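# End-to-end pipeline configuration and execution, plus network export in
# standard graph formats.

#' Pipeline configuration
#'
#' Validates and collects every tunable of the end-to-end analysis. Either
#' the three input paths (`events`, `patients`, `catalog`) or a
#' [synthetic_spec()] (`simulate`) must be supplied.
#'
#' @param output_dir Directory for all artifacts (created if missing).
#' @param events,patients,catalog Input CSV paths, or `NULL` when simulating.
#' @param simulate Optional [synthetic_spec()]; when given, the pipeline
#'   generates its own input data first.
#' @param t2dm_code_set Codes identifying T2DM (index-date definition).
#' @param min_prevalence Condition prevalence floor (fraction in (0, 1\]).
#' @param t_critical Pair-significance critical value (default 2.58).
#' @param burst_threshold Degree-growth threshold for burst diseases.
#' @param damping PageRank damping factor.
#' @param louvain_restarts Louvain restarts.
#' @param top_k Hub list size.
#' @param perturb_levels,perturb_reps Edge-removal levels and replicates.
#' @param temporal_first,temporal_baseline,temporal_end Study/baseline/end
#'   years for the cumulative yearly networks.
#' @param min_stratum_patients Minimum patients per age stratum.
#' @param seed Master seed; fans out deterministically to every stage.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(output_dir,
                            events = NULL, patients = NULL, catalog = NULL,
                            simulate = NULL,
                            t2dm_code_set = "E11",
                            min_prevalence = 0.01,
                            t_critical = 2.58,
                            burst_threshold = 6,
                            damping = 0.85,
                            louvain_restarts = 20,
                            top_k = 10,
                            perturb_levels = c(0.01, 0.03, 0.05),
                            perturb_reps = 3,
                            temporal_first = 2013,
                            temporal_baseline = 2015,
                            temporal_end = 2021,
                            min_stratum_patients = 30,
                            seed = 1L) {
  fail <- function(field, why) {
    stop(sprintf("invalid pipeline_config field '%s': %s", field, why), call. = FALSE)
  }
  if (is.null(simulate) && (is.null(events) || is.null(patients) || is.null(catalog)))
    fail("events/patients/catalog", "input paths required unless 'simulate' is given")
  if (!is.null(simulate)) validate_synthetic_spec(simulate)
  if (!is.numeric(min_prevalence) || min_prevalence <= 0 || min_prevalence > 1)
    fail("min_prevalence", "must be a fraction in (0, 1]; percentages are not accepted")
  if (!is.numeric(t_critical) || t_critical <= 0) fail("t_critical", "must be positive")
  if (!is.numeric(burst_threshold) || burst_threshold < 1)
    fail("burst_threshold", "must be >= 1")
  if (!is.numeric(damping) || damping <= 0 || damping >= 1)
    fail("damping", "must be in (0, 1)")
  if (any(perturb_levels < 0) || any(perturb_levels > 1))
    fail("perturb_levels", "must be fractions in [0, 1]")
  if (temporal_first > temporal_baseline || temporal_baseline > temporal_end)
    fail("temporal_*", "must satisfy first <= baseline <= end")
  cfg <- list(
    output_dir = output_dir, events = events, patients = patients,
    catalog = catalog, simulate = simulate, t2dm_code_set = t2dm_code_set,
    min_prevalence = min_prevalence, t_critical = t_critical,
    burst_threshold = burst_threshold, damping = damping,
    louvain_restarts = as.integer(louvain_restarts), top_k = as.integer(top_k),
    perturb_levels = perturb_levels, perturb_reps = as.integer(perturb_reps),
    temporal_first = as.integer(temporal_first),
    temporal_baseline = as.integer(temporal_baseline),
    temporal_end = as.integer(temporal_end),
    min_stratum_patients = as.integer(min_stratum_patients),
    seed = as.integer(seed)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
}

#' Run the full multimorbidity-network pipeline
#'
#' Executes cohort building, network construction (global per sex plus sex x
#' age strata), network metrics, crucial-disease identification, temporal
#' degree trends, and perturbation analyses, writing every artifact plus a
#' run manifest under `config$output_dir`. All randomness derives from
#' `config$seed`, so a rerun with the same config is byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the principal in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)

  if (!is.null(config$simulate)) {
    sim_dir <- out("synthetic")
    sim <- generate_synthetic_cohort(config$simulate, dir = sim_dir)
    events_path <- sim$paths$events
    patients_path <- sim$paths$patients
    catalog_path <- sim$paths$catalog
  } else {
    events_path <- config$events
    patients_path <- config$patients
    catalog_path <- config$catalog
  }

  loaded <- suppressWarnings(load_records(events_path, patients_path, catalog_path))
  elig <- apply_eligibility(loaded$events, loaded$patients)
  ia <- compute_index_and_age(loaded$events, elig$eligible, config$t2dm_code_set)
  cohort <- ia$cohort
  exclusions <- data.table::rbindlist(list(elig$exclusions, ia$exclusions))
  sel <- select_conditions(loaded$events, cohort, loaded$catalog,
                           min_prevalence = config$min_prevalence)

  data.table::fwrite(cohort, out("cohort.csv"))
  data.table::fwrite(exclusions, out("exclusions.csv"))
  data.table::fwrite(sel$universe, out("condition_universe.csv"))
  data.table::fwrite(sel$condition_sets, out("condition_sets.csv"))
  data.table::fwrite(sel$prevalence, out("condition_prevalence.csv"))

  nets <- build_stratified_networks(
    cohort, sel$condition_sets, sel$universe$code,
    chronic_codes = sel$chronic_codes, t_critical = config$t_critical,
    min_patients = config$min_stratum_patients)

  dir.create(out("networks"), showWarnings = FALSE)
  dir.create(out("pair_stats"), showWarnings = FALSE)
  summaries <- list()
  for (label in names(nets)) {
    slug <- gsub(":", "_", label)
    res <- nets[[label]]
    data.table::fwrite(res$stats, out("pair_stats", paste0(slug, ".csv")))
    export_network(res$network, out("networks", paste0(slug, ".csv")), "edgelist_csv")
    .write_json(list(stratum = label, N = res$N, q = res$cutoff$q, e = res$cutoff$e,
                     mean_cij = res$cutoff$mean_cij, sci_cutoff = res$cutoff$sci_cutoff),
                out("networks", paste0(slug, "_cutoff.json")))
    summaries[[label]] <- summarize_network(res$network)
    deg <- compute_degrees(res$network)
    hc <- compute_harmonic_centrality(res$network, normalized = TRUE)
    deg[, harmonic := as.numeric(hc[code])]
    data.table::fwrite(deg, out("networks", paste0(slug, "_node_metrics.csv")))
  }
  .write_json(summaries, out("network_summaries.json"))

  report <- list()
  for (s in c("male", "female")) {
    glabel <- paste0(s, ":global")
    if (is.null(nets[[glabel]]) || igraph::ecount(nets[[glabel]]$network) == 0) next
    g <- nets[[glabel]]$network
    export_network(g, out("networks", paste0(s, "_global.graphml")), "graphml")
    export_network(g, out("networks", paste0(s, "_global.gexf")), "gexf")
    band_nets <- list()
    for (b in age_band_labels()) {
      blabel <- paste(s, b, sep = ":")
      if (!is.null(nets[[blabel]])) band_nets[[b]] <- nets[[blabel]]$network
    }
    rep_s <- suppressWarnings(crucial_disease_report(
      g, band_nets, k = config$top_k, damping = config$damping,
      burst_threshold = config$burst_threshold,
      seed = derive_seed(config$seed, 10L + match(s, c("male", "female"))),
      n_restarts = config$louvain_restarts))
    report[[s]] <- rep_s

    comm_dt <- data.table::data.table(
      code = names(rep_s$communities$membership),
      community = as.integer(rep_s$communities$membership))
    comm_dt[, is_root := code %in% rep_s$roots$root]
    data.table::fwrite(comm_dt, out(paste0("communities_", s, ".csv")))
    data.table::fwrite(rep_s$hubs, out(paste0("hubs_", s, ".csv")))
    data.table::fwrite(rep_s$bursts$trajectories, out(paste0("burst_trajectories_", s, ".csv")))
    data.table::fwrite(rep_s$bursts$bursts, out(paste0("bursts_", s, ".csv")))
  }
  .write_json(lapply(report, function(r) list(
    hubs = r$hubs$code, roots = r$roots$root,
    bursts = unique(r$bursts$bursts$code), cores = r$cores,
    modularity = r$communities$modularity)),
    out("crucial_report.json"))

  temporal <- suppressWarnings(temporal_degree_trends(
    loaded$events, cohort, condition_universe = sel$universe$code,
    chronic_codes = sel$chronic_codes,
    first_year = config$temporal_first, baseline_year = config$temporal_baseline,
    end_year = config$temporal_end, t_critical = config$t_critical))
  if (nrow(temporal$degree_table) > 0) {
    data.table::fwrite(temporal$degree_table, out("temporal_degrees.csv"))
  }

  perturb_nodes <- list()
  perturb_edges <- list()
  for (s in names(report)) {
    g <- nets[[paste0(s, ":global")]]$network
    crucial <- sort(unique(c(report[[s]]$hubs$code, report[[s]]$roots$root,
                             unique(report[[s]]$bursts$bursts$code))))
    crucial <- intersect(crucial, igraph::V(g)$name)
    if (length(crucial)) {
      nr <- node_removal_analysis(g, crucial)
      nr[, sex := s]
      perturb_nodes[[s]] <- nr
    }
    if (igraph::ecount(g) >= 1 / min(config$perturb_levels[config$perturb_levels > 0])) {
      er <- suppressWarnings(edge_removal_analysis(
        g, levels = config$perturb_levels, reps = config$perturb_reps,
        k = config$top_k, seed = derive_seed(config$seed, 20L + match(s, c("male", "female"))),
        damping = config$damping))
      er[, sex := s]
      perturb_edges[[s]] <- er
    }
  }
  if (length(perturb_nodes)) {
    data.table::fwrite(data.table::rbindlist(perturb_nodes, fill = TRUE),
                       out("perturbation_nodes.csv"))
  }
  if (length(perturb_edges)) {
    data.table::fwrite(data.table::rbindlist(perturb_edges),
                       out("perturbation_edges.csv"))
  }

  # paths are environment-specific: keep only basenames in the manifest so a
  # rerun of the same analysis in another directory is byte-identical
  cfg_serial <- config
  cfg_serial$simulate <- if (!is.null(config$simulate)) unclass(config$simulate) else NULL
  cfg_serial$output_dir <- NULL
  for (f in c("events", "patients", "catalog")) {
    if (!is.null(cfg_serial[[f]])) cfg_serial[[f]] <- basename(cfg_serial[[f]])
  }
  manifest <- list(
    package = "mmnet",
    version = as.character(utils::packageVersion("mmnet")),
    seed = config$seed,
    config = unclass(cfg_serial),
    n_patients_cohort = nrow(cohort),
    n_conditions_universe = nrow(sel$universe),
    strata = names(nets)
  )
  .write_json(manifest, out("manifest.json"))

  invisible(list(cohort = cohort, selection = sel, networks = nets,
                 report = report, temporal = temporal, manifest = manifest))
}

# ---- network export / import --------------------------------------------

.fmt_num <- function(x) sprintf("%.17g", x)

#' Export a network to GraphML, GEXF, or edge-list CSV
#'
#' The SCI weight is stored as edge attribute `sci` (and as the GEXF edge
#' `weight`), written at full double precision so a round-trip import
#' reproduces the graph exactly.
#'
#' @param network An `igraph` graph with `weight` edge attribute.
#' @param path Output file path.
#' @param format One of `"graphml"`, `"gexf"`, `"edgelist_csv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("graphml", "gexf", "edgelist_csv")) {
  if (!is.character(format) || !format[1] %in% c("graphml", "gexf", "edgelist_csv")) {
    stop(sprintf("unknown format '%s'; supported formats: graphml, gexf, edgelist_csv",
                 format[1]), call. = FALSE)
  }
  format <- format[1]
  el <- igraph::as_data_frame(network, what = "edges")
  nodes <- igraph::V(network)$name %||% character(0)
  if (format == "edgelist_csv") {
    dt <- data.table::data.table(code_i = el$from, code_j = el$to,
                                 sci = .fmt_num(el$weight))
    data.table::fwrite(dt, path, quote = FALSE)
  } else if (format == "graphml") {
    lines <- c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '  <key id="sci" for="edge" attr.name="sci" attr.type="double"/>',
      '  <graph id="G" edgedefault="undirected">',
      sprintf('    <node id="%s"/>', nodes),
      if (nrow(el)) sprintf('    <edge source="%s" target="%s"><data key="sci">%s</data></edge>',
                            el$from, el$to, .fmt_num(el$weight)),
      "  </graph>", "</graphml>")
    writeLines(lines, path)
  } else {
    lines <- c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
      '  <graph defaultedgetype="undirected">',
      '    <attributes class="edge">',
      '      <attribute id="0" title="sci" type="double"/>',
      "    </attributes>",
      "    <nodes>",
      sprintf('      <node id="%s" label="%s"/>', nodes, nodes),
      "    </nodes>",
      "    <edges>",
      if (nrow(el)) sprintf(paste0('      <edge id="%d" source="%s" target="%s" weight="%s">',
                                   '<attvalues><attvalue for="0" value="%s"/></attvalues></edge>'),
                            seq_len(nrow(el)) - 1L, el$from, el$to,
                            .fmt_num(el$weight), .fmt_num(el$weight)),
      "    </edges>", "  </graph>", "</gexf>")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Import a network written by [export_network()]
#'
#' @param path File path.
#' @param format One of `"graphml"`, `"gexf"`, `"edgelist_csv"`.
#' @return An `igraph` graph with `weight` edge attribute (= SCI).
#' @export
import_network <- function(path, format = c("graphml", "gexf", "edgelist_csv")) {
  if (!is.character(format) || !format[1] %in% c("graphml", "gexf", "edgelist_csv")) {
    stop(sprintf("unknown format '%s'; supported formats: graphml, gexf, edgelist_csv",
                 format[1]), call. = FALSE)
  }
  format <- format[1]
  if (format == "edgelist_csv") {
    dt <- data.table::fread(path, colClasses = list(character = c("code_i", "code_j")))
    if (nrow(dt) == 0) return(igraph::make_empty_graph(0, directed = FALSE))
    return(igraph::graph_from_data_frame(
      data.frame(from = dt$code_i, to = dt$code_j, weight = as.numeric(dt$sci)),
      directed = FALSE))
  }
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  node_ids <- xml2::xml_attr(xml2::xml_find_all(doc, ".//node"), "id")
  edges <- xml2::xml_find_all(doc, ".//edge")
  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, length(node_ids), name = node_ids)
  if (length(edges)) {
    from <- xml2::xml_attr(edges, "source")
    to <- xml2::xml_attr(edges, "target")
    w <- if (format == "graphml") {
      as.numeric(xml2::xml_text(xml2::xml_find_first(edges, "./data[@key='sci']")))
    } else {
      as.numeric(xml2::xml_attr(xml2::xml_find_all(edges, ".//attvalue"), "value"))
    }
    g <- igraph::add_edges(g, rbind(match(from, node_ids), match(to, node_ids)))
    igraph::E(g)$weight <- w
  }
  g
}
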