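# Topological indices. All distance-based indices are computed per
# connected component: unreachable pairs are excluded (not infinite),
# matching NetworkAnalyzer. Degenerate cases (singleton components,
# degree < 2) yield 0.

CENTRALITY_COLUMNS <- c(
  "MNC", "EPC", "Bottleneck", "BetweennessCentrality",
  "ClosenessCentrality", "Degree", "Radiality", "Stress",
  "AverageShortestPathLength", "ClusteringCoefficient",
  "NeighborhoodConnectivity", "TopologicalCoefficient",
  "NumberOfUndirectedEdges", "Betweenness"
)

#' Names and rank directions of the topological feature set
#'
#' The fourteen per-node indices the pipeline extracts from a PPI network,
#' split by biological reading: for eleven indices larger values mean more
#' central; for the three path/modularity indices
#' (`AverageShortestPathLength`, `TopologicalCoefficient`,
#' `ClusteringCoefficient`) smaller values mean more hub-like.
#'
#' @return `centrality_columns()`: all 14 column names;
#'   `default_descending_indices()` / `default_ascending_indices()`: the
#'   default direction partition used by [composite_score()].
#' @export
centrality_columns <- function() CENTRALITY_COLUMNS

#' @rdname centrality_columns
#' @export
default_ascending_indices <- function() {
  c("AverageShortestPathLength", "TopologicalCoefficient", "ClusteringCoefficient")
}

#' @rdname centrality_columns
#' @export
default_descending_indices <- function() {
  setdiff(CENTRALITY_COLUMNS, default_ascending_indices())
}

# distance matrix with -1 recoded as NA (unreachable)
dist_matrix <- function(g) {
  D <- cpp_all_pairs_dist(g$adj, length(g$nodes))
  D[D < 0] <- NA_integer_
  dimnames(D) <- list(g$nodes, g$nodes)
  D
}

# Whole-graph computation of all deterministic indices; returns a list of
# named numeric vectors. EPC is separate (stochastic).
compute_indices <- function(g) {
  n <- length(g$nodes)
  A <- adjacency_matrix(g)
  deg <- rowSums(A)
  D <- dist_matrix(g)
  comp <- graph_components(g)
  comp_size <- tabulate(comp)[comp]

  finite <- !is.na(D)
  reach <- finite & D > 0
  r <- rowSums(reach)                       # reachable nodes excluding self
  sumd <- rowSums(D * reach, na.rm = TRUE)  # total geodesic distance

  closeness <- ifelse(r == 0, 0, r / sumd)
  aspl <- ifelse(r == 0, 0, sumd / r)

  # component diameters
  diam_by_comp <- vapply(
    split(as.vector(D[finite]), rep(comp, times = n)[as.vector(finite)]),
    max, numeric(1)
  )
  diam <- diam_by_comp[as.character(comp)]
  radiality <- ifelse(
    comp_size <= 1, 0,
    ((diam + 1) * r - sumd) / (comp_size - 1)
  )

  br <- cpp_brandes(g$adj, n)
  betweenness <- br$betweenness
  stress <- br$stress
  bc_norm <- ifelse(
    comp_size >= 3,
    betweenness * 2 / ((comp_size - 1) * (comp_size - 2)),
    0
  )

  A2 <- A %*% A
  triangles <- diag(A2 %*% A)
  clustering <- ifelse(deg < 2, 0, triangles / (deg * (deg - 1)))

  neigh_conn <- ifelse(deg == 0, 0, as.vector(A %*% deg) / deg)

  # topological coefficient: partners share >= 1 neighbor; +1 when adjacent
  shared <- A2
  diag(shared) <- 0
  partners <- shared > 0
  n_partners <- rowSums(partners)
  J <- (shared + A) * partners
  tc <- ifelse(
    n_partners == 0 | deg < 1, 0,
    rowSums(J) / (n_partners * deg)
  )

  mnc <- vapply(seq_len(n), function(v) {
    nb <- g$adj[[v]]
    if (length(nb) == 0L) return(0)
    sub <- A[nb, nb, drop = FALSE]
    max(component_sizes_dense(sub))
  }, numeric(1))

  bottleneck <- as.numeric(cpp_bottleneck(g$adj, n))

  out <- list(
    MNC = mnc,
    Bottleneck = bottleneck,
    BetweennessCentrality = bc_norm,
    ClosenessCentrality = closeness,
    Degree = deg,
    Radiality = radiality,
    Stress = stress,
    AverageShortestPathLength = aspl,
    ClusteringCoefficient = clustering,
    NeighborhoodConnectivity = neigh_conn,
    TopologicalCoefficient = tc,
    NumberOfUndirectedEdges = deg,
    Betweenness = betweenness
  )
  lapply(out, function(x) stats::setNames(as.numeric(x), g$nodes))
}

# component sizes of a small dense adjacency matrix (induced subgraph scan)
component_sizes_dense <- function(A) {
  m <- nrow(A)
  if (m == 0L) return(0L)
  seen <- rep(FALSE, m)
  sizes <- integer(0)
  for (s in seq_len(m)) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    sz <- 0L
    while (length(queue) > 0L) {
      u <- queue[[1]]
      queue <- queue[-1]
      sz <- sz + 1L
      nb <- which(A[u, ] > 0 & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    sizes <- c(sizes, sz)
  }
  sizes
}

index_vector <- function(g, what, v = NULL) {
  vals <- compute_indices(g)[[what]]
  if (is.null(v)) vals else unname(vals[node_index(g, v)])
}

#' Per-node topological indices
#'
#' Each function computes one of the fourteen topological indices for all
#' nodes (named vector) or for the nodes named in `v`. Distance-based
#' indices are restricted to the node's connected component; degenerate
#' inputs (singleton components, degree below 2) return 0.
#'
#' * `node_degree()` — number of distinct neighbors.
#' * `node_closeness()` — reachable-node count divided by total geodesic
#'   distance.
#' * `node_avg_shortest_path()` — mean geodesic distance to reachable nodes.
#' * `node_radiality()` — mean of `diameter + 1 - d(v, w)` over the
#'   component.
#' * `node_betweenness()` — raw shortest-path betweenness over unordered
#'   pairs; `normalized = TRUE` rescales by `2 / ((n-1)(n-2))` with `n` the
#'   component size.
#' * `node_stress()` — number of geodesics with the node in their interior.
#' * `node_clustering()` — transitivity of the neighborhood.
#' * `node_neighborhood_connectivity()` — mean neighbor degree.
#' * `node_topological_coefficient()` — normalized shared-neighbor count
#'   over partner nodes (shared neighbors, +1 when directly adjacent).
#' * `node_mnc()` — size of the largest connected component among the
#'   node's neighbors.
#' * `node_bottleneck()` — number of BFS shortest-path trees (smallest-symbol
#'   parent tie-break) in which the node's subtree exceeds a quarter of the
#'   component.
#' * `node_epc()` — Monte-Carlo edge-percolated component: mean size of the
#'   node's component when each edge is retained independently with
#'   probability `retain_p`.
#'
#' @param g A [ppi_graph][as_ppi_graph].
#' @param v Optional node symbol(s); default all nodes.
#' @return Named numeric vector (all nodes) or unnamed numeric (for `v`).
#' @examples
#' g <- as_ppi_graph(data.frame(a = c("A", "B"), b = c("B", "C")))
#' node_degree(g, "B")
#' node_betweenness(g)
#' @export
node_degree <- function(g, v = NULL) index_vector(g, "Degree", v)

#' @rdname node_degree
#' @export
node_closeness <- function(g, v = NULL) index_vector(g, "ClosenessCentrality", v)

#' @rdname node_degree
#' @export
node_avg_shortest_path <- function(g, v = NULL) {
  index_vector(g, "AverageShortestPathLength", v)
}

#' @rdname node_degree
#' @export
node_radiality <- function(g, v = NULL) index_vector(g, "Radiality", v)

#' @rdname node_degree
#' @param normalized Return the component-size-normalized variant?
#' @export
node_betweenness <- function(g, v = NULL, normalized = FALSE) {
  index_vector(g, if (normalized) "BetweennessCentrality" else "Betweenness", v)
}

#' @rdname node_degree
#' @export
node_stress <- function(g, v = NULL) index_vector(g, "Stress", v)

#' @rdname node_degree
#' @export
node_clustering <- function(g, v = NULL) index_vector(g, "ClusteringCoefficient", v)

#' @rdname node_degree
#' @export
node_neighborhood_connectivity <- function(g, v = NULL) {
  index_vector(g, "NeighborhoodConnectivity", v)
}

#' @rdname node_degree
#' @export
node_topological_coefficient <- function(g, v = NULL) {
  index_vector(g, "TopologicalCoefficient", v)
}

#' @rdname node_degree
#' @export
node_mnc <- function(g, v = NULL) index_vector(g, "MNC", v)

#' @rdname node_degree
#' @export
node_bottleneck <- function(g, v = NULL) index_vector(g, "Bottleneck", v)

#' @rdname node_degree
#' @param retain_p Edge retention probability for the percolation draws.
#' @param iterations Number of Monte-Carlo percolation draws.
#' @param seed RNG seed (the estimate is deterministic given the seed).
#' @export
node_epc <- function(g, v = NULL, retain_p = 0.5, iterations = 1000, seed = 42) {
  stopifnot(
    is.numeric(retain_p), retain_p >= 0, retain_p <= 1,
    iterations >= 1
  )
  vals <- withr::with_seed(seed, {
    cpp_epc(g$edges, length(g$nodes), retain_p, as.integer(iterations))
  })
  vals <- stats::setNames(as.numeric(vals), g$nodes)
  if (is.null(v)) vals else unname(vals[node_index(g, v)])
}

#' Full per-gene centrality table
#'
#' Computes all fourteen topological indices for every node and assembles
#' the feature table used downstream (one row per gene, the exact
#' NetworkAnalyzer/CytoNCA column names). `Degree` and
#' `NumberOfUndirectedEdges` coincide on simple graphs but are both kept so
#' the exported feature set has the full fourteen columns;
#' `BetweennessCentrality` is the component-normalized twin of the raw
#' `Betweenness` count.
#'
#' @inheritParams node_epc
#' @return A tibble: `gene` plus the 14 index columns, one row per node in
#'   lexicographic order.
#' @examples
#' g <- as_ppi_graph(data.frame(a = c("A", "B"), b = c("B", "C")))
#' centrality_table(g, epc_iterations = 100)
#' @export
centrality_table <- function(g, epc_retain_p = 0.5, epc_iterations = 1000, seed = 42) {
  stopifnot(inherits(g, "ppi_graph"))
  det <- compute_indices(g)
  epc <- node_epc(g, retain_p = epc_retain_p, iterations = epc_iterations, seed = seed)
  cols <- c(list(EPC = epc), det)[CENTRALITY_COLUMNS]
  tibble::as_tibble(c(list(gene = g$nodes), lapply(cols, unname)))
}

#' @rdname node_epc
#' @export
epc_retain_defaults <- function() list(retain_p = 0.5, iterations = 1000)

#' Intersect per-metric hub lists
#'
#' Ranks genes by each of the chosen centrality metrics, takes the top `k`
#' per metric (ties with the k-th value are all included, so the selection
#' is order-independent and nested in `k`), and intersects the lists. The
#' result is ordered by mean fractional rank across the chosen metrics.
#'
#' @param table A centrality table from [centrality_table()] (or any tibble
#'   with a `gene` column and numeric metric columns).
#' @param metrics Metric column names to intersect (default the four-index
#'   panel MNC, EPC, Bottleneck, Betweenness).
#' @param top_k How many top genes to take per metric.
#' @return A [gene_list] of intersecting hub genes, most central first.
#' @export
hub_intersection <- function(table,
                             metrics = c("MNC", "EPC", "Bottleneck", "Betweenness"),
                             top_k) {
  stopifnot(is.data.frame(table), "gene" %in% names(table))
  missing_cols <- setdiff(metrics, names(table))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "Metrics not present in the table: %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  n <- nrow(table)
  if (!is.numeric(top_k) || length(top_k) != 1 || top_k < 1 || top_k > n) {
    abort(sprintf("`top_k` must be in [1, %d].", n), class = "netprio_parameter_error")
  }
  sets <- lapply(metrics, function(m) {
    vals <- table[[m]]
    thr <- sort(vals, decreasing = TRUE)[top_k]
    table$gene[vals >= thr]
  })
  common <- Reduce(intersect, sets)
  if (length(common) == 0) {
    return(gene_list(character(), name = "hub_intersection"))
  }
  ranks <- vapply(metrics, function(m) frank(table[[m]], descending = TRUE), numeric(n))
  mean_rank <- rowMeans(ranks)[match(common, table$gene)]
  gene_list(common[order(mean_rank, common, method = "radix")], name = "hub_intersection")
}
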