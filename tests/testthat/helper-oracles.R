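# Independent brute-force oracles. These deliberately avoid the package's
# code paths (and igraph) so that agreement is a genuine cross-check:
# counting by double loops over patients, distances by hand-rolled BFS,
# PageRank / eigenvector centrality by dense power iteration.

# -- contingency counting by brute force ----------------------------------

# sets: named list patient_id -> character vector of codes
oracle_counts <- function(sets, universe, n_patients, chronic_codes = NULL) {
  sets <- lapply(sets, function(s) sort(intersect(unique(s), universe)))
  codes <- sort(unique(unlist(sets)))
  marg <- sapply(codes, function(cd) sum(vapply(sets, function(s) cd %in% s, logical(1))))
  pair_rows <- list()
  for (p in names(sets)) {
    s <- sets[[p]]
    if (length(s) < 2) next
    if (!is.null(chronic_codes) && !any(s %in% chronic_codes)) next
    pr <- t(combn(s, 2))
    pair_rows[[p]] <- pr
  }
  if (length(pair_rows)) {
    allp <- do.call(rbind, pair_rows)
    key <- paste(allp[, 1], allp[, 2], sep = "|")
    tab <- table(key)
    parts <- do.call(rbind, strsplit(names(tab), "|", fixed = TRUE))
    pairs <- data.frame(code_i = parts[, 1], code_j = parts[, 2],
                        c_ij = as.integer(tab), stringsAsFactors = FALSE)
    pairs$c_i <- as.integer(marg[pairs$code_i])
    pairs$c_j <- as.integer(marg[pairs$code_j])
    pairs <- pairs[order(pairs$code_i, pairs$code_j), ]
    rownames(pairs) <- NULL
  } else {
    pairs <- data.frame(code_i = character(), code_j = character(),
                        c_ij = integer(), c_i = integer(), c_j = integer())
  }
  list(N = n_patients, marginals = marg, pairs = pairs)
}

# -- pair statistics written out longhand ---------------------------------

oracle_pair_stats <- function(ci, cj, cij, N) {
  sci <- cij / sqrt(ci * cj)
  if (ci >= N || cj >= N) {
    return(list(sci = sci, phi = NA_real_, t = NA_real_, valid = FALSE))
  }
  phi <- (cij * N - ci * cj) / sqrt(ci * cj * (N - ci) * (N - cj))
  t <- if (cij <= 2) 0 else if (abs(phi) >= 1) sign(phi) * Inf else
    phi * sqrt(cij - 2) / sqrt(1 - phi^2)
  list(sci = sci, phi = phi, t = t, valid = TRUE)
}

# -- the 4-step cutoff, applied literally to a data frame ------------------

oracle_cutoff <- function(df, t_critical = 2.58) {
  df <- df[df$valid & df$c_ij > 0, ]
  q <- nrow(df)
  if (q == 0) return(list(q = 0L, e = 0L, retained = df))
  mean_cij <- sum(df$c_ij) / q
  pass <- df$t > t_critical & df$c_ij > mean_cij
  e <- sum(pass)
  if (e == 0) return(list(q = q, e = 0L, retained = df[0, ]))
  ord <- order(df$sci, decreasing = TRUE)
  cutoff <- df$sci[ord][e]
  retained <- df[df$sci >= cutoff, ]
  retained <- retained[order(retained$code_i, retained$code_j), ]
  rownames(retained) <- NULL
  list(q = q, e = e, mean_cij = mean_cij, sci_cutoff = cutoff, retained = retained)
}

# -- graph oracles on adjacency matrices ----------------------------------

# adjacency (weighted, symmetric) from an igraph object, for oracle use only
adj_of <- function(g) {
  igraph::as_adjacency_matrix(g, attr = if ("weight" %in%
    igraph::edge_attr_names(g)) "weight" else NULL, sparse = FALSE)
}

# all-pairs BFS hop distances on a 0/1 adjacency; Inf when unreachable
oracle_bfs_dist <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(A[v, ] > 0)
        new <- nb[dist[nb] == Inf]
        dist[new] <- d
        nxt <- c(nxt, new)
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
  }
  D
}

oracle_harmonic <- function(A) {
  D <- oracle_bfs_dist(A)
  diag(D) <- Inf
  rowSums(1 / D)
}

# weighted PageRank by dense power iteration; dangling mass spread uniformly
oracle_pagerank <- function(A, damping = 0.85, tol = 1e-14, max_iter = 100000) {
  n <- nrow(A)
  s <- rowSums(A)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (s[i] > 0) P[i, ] <- A[i, ] / s[i]
  }
  dangling <- s == 0
  x <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    x_new <- damping * (as.vector(x %*% P) + sum(x[dangling]) / n) + (1 - damping) / n
    if (sum(abs(x_new - x)) < tol) return(x_new)
    x <- x_new
  }
  x
}

# leading eigenvector of a symmetric non-negative matrix by power iteration,
# scaled so the maximum entry is 1 (the igraph convention)
oracle_eigen <- function(A, tol = 1e-14, max_iter = 100000) {
  n <- nrow(A)
  x <- rep(1, n)
  for (it in seq_len(max_iter)) {
    y <- as.vector(A %*% x)
    if (max(abs(y)) == 0) return(rep(0, n))
    y <- y / sqrt(sum(y^2))
    if (sum(abs(y - x)) < tol) break
    x <- y
  }
  y / max(y)
}

# -- fixture builders ------------------------------------------------------

# random per-patient condition sets (no planted structure)
random_condition_sets <- function(n_patients, codes, mean_conditions = 4, seed = 1) {
  set.seed(seed)
  sets <- lapply(seq_len(n_patients), function(i) {
    k <- min(length(codes), rpois(1, mean_conditions))
    if (k == 0) character(0) else sample(codes, k)
  })
  names(sets) <- sprintf("P%04d", seq_len(n_patients))
  sets
}

sets_to_dt <- function(sets) {
  data.table::rbindlist(lapply(names(sets), function(p) {
    if (!length(sets[[p]])) return(NULL)
    data.table::data.table(patient_id = p, code = sets[[p]])
  }))
}

# connected random weighted graph: ER edges plus a random spanning cycle
random_weighted_graph <- function(n, p = 0.15, seed = 1) {
  set.seed(seed)
  A <- matrix(0, n, n)
  perm <- sample(n)
  for (i in seq_len(n)) {
    a <- perm[i]; b <- perm[if (i == n) 1 else i + 1]
    A[a, b] <- A[b, a] <- runif(1, 0.1, 1)
  }
  extra <- which(upper.tri(A) & matrix(runif(n * n), n, n) < p, arr.ind = TRUE)
  for (k in seq_len(nrow(extra))) {
    i <- extra[k, 1]; j <- extra[k, 2]
    if (A[i, j] == 0) A[i, j] <- A[j, i] <- runif(1, 0.1, 1)
  }
  dimnames(A) <- list(sprintf("N%02d", 1:n), sprintf("N%02d", 1:n))
  igraph::graph_from_adjacency_matrix(A, mode = "undirected", weighted = TRUE)
}

# age-band networks in which one focal node "F" has a prescribed degree:
# star graphs, used to exercise the burst-detection rule
band_nets_from_degrees <- function(deg_by_band) {
  lapply(deg_by_band, function(d) {
    if (d == 0) {
      g <- igraph::make_graph(c("X1", "X2"), directed = FALSE)
    } else {
      leaves <- sprintf("L%02d", seq_len(d))
      g <- igraph::make_graph(as.vector(rbind("F", leaves)), directed = FALSE)
    }
    igraph::E(g)$weight <- 0.5
    g
  })
}

# planted-hub network via the synthetic generator (condition-matrix route)
planted_network <- function(seed, n_patients = 5000, n_conditions = 60,
                            n_clusters = 4, cluster_effect = 4,
                            hub_conditions = c(1, 2)) {
  spec <- mmnet::synthetic_spec(
    n_patients = n_patients, n_conditions = n_conditions,
    n_clusters = n_clusters, cluster_effect = cluster_effect,
    hub_conditions = hub_conditions, seed = seed)
  sm <- mmnet::simulate_condition_matrix(spec)
  idx <- which(sm$incidence == 1, arr.ind = TRUE)
  sets <- data.table::data.table(
    patient_id = sprintf("P%06d", idx[, 1]),
    code = colnames(sm$incidence)[idx[, 2]])
  counts <- mmnet::contingency_counts(sets, colnames(sm$incidence), nrow(sm$incidence))
  stats <- mmnet::pair_statistics(counts)
  cutoff <- mmnet::determine_sci_cutoff(stats)
  list(network = mmnet::build_network(cutoff), truth = sm$truth,
       stats = stats, cutoff = cutoff)
}
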