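# Seeded synthetic-data generators with known ground truth. Filler gene
# symbols are "G000001"-style; planted entities carry grep-able names
# ("HUB1", "ENRICHED_SET1"). Every generator is a pure function of its
# parameters and seed.

filler_symbols <- function(n) sprintf("G%06d", seq_len(n))

#' Generate a scale-free PPI-like network with planted super-hubs
#'
#' Grows a connected preferential-attachment (Barabasi-Albert style)
#' network — each new node attaches to `edges_per_new_node` existing nodes
#' with probability proportional to degree — and then plants `n_hubs`
#' super-hub genes by giving randomly chosen nodes `hub_extra_degree`
#' additional attachments to uniformly drawn non-neighbors. Degree
#' heterogeneity (not biological realism) is the point: it is the signal
#' the composite score must recover.
#'
#' @param n_nodes Total number of nodes (>= 10). Default 364, matching a
#'   mid-sized disease-target PPI.
#' @param edges_per_new_node Attachments per arriving node. Default 2.
#' @param n_hubs Number of planted super-hubs. Default 5.
#' @param hub_extra_degree Extra attachments per planted hub. Default 40.
#' @param seed RNG seed.
#' @return A list: `graph` (a [ppi_graph][as_ppi_graph]) and `truth`
#'   (planted hub symbols + generation parameters).
#' @examples
#' sim <- generate_ppi(n_nodes = 50, n_hubs = 2, hub_extra_degree = 15, seed = 1)
#' sim$truth$planted_hub_genes
#' @export
generate_ppi <- function(n_nodes = 364, edges_per_new_node = 2, n_hubs = 5,
                         hub_extra_degree = 40, seed = 42) {
  stopifnot(n_nodes >= 10, edges_per_new_node >= 1, n_hubs >= 0, n_hubs < n_nodes)
  withr::with_seed(as.integer(seed), {
    names_all <- filler_symbols(n_nodes)
    hub_pos <- if (n_hubs > 0) sort(sample.int(n_nodes, n_hubs)) else integer()
    names_all[hub_pos] <- paste0("HUB", seq_along(hub_pos))

    deg <- integer(n_nodes)
    m_max <- edges_per_new_node * (n_nodes - 2) + 1 + n_hubs * hub_extra_degree
    ei <- integer(m_max)
    ej <- integer(m_max)
    ne <- 0L
    add_edge <- function(a, b) {
      ne <<- ne + 1L
      ei[ne] <<- a
      ej[ne] <<- b
      deg[a] <<- deg[a] + 1L
      deg[b] <<- deg[b] + 1L
    }
    add_edge(1L, 2L)
    for (t in 3:n_nodes) {
      m <- min(edges_per_new_node, t - 1L)
      targets <- sample.int(t - 1L, m, prob = deg[seq_len(t - 1L)])
      for (u in targets) add_edge(u, t)
    }
    # plant the hubs: extra uniform attachments to current non-neighbors
    for (h in hub_pos) {
      nbrs <- unique(c(ej[seq_len(ne)][ei[seq_len(ne)] == h],
                       ei[seq_len(ne)][ej[seq_len(ne)] == h]))
      candidates <- setdiff(seq_len(n_nodes), c(h, nbrs))
      extra <- sample_safe(candidates, min(hub_extra_degree, length(candidates)))
      for (u in extra) add_edge(h, u)
    }
    edges <- data.frame(
      from = names_all[ei[seq_len(ne)]],
      to = names_all[ej[seq_len(ne)]]
    )
    graph <- as_ppi_graph(edges)
    truth <- list(
      planted_hub_genes = names_all[hub_pos],
      params = list(
        n_nodes = n_nodes, edges_per_new_node = edges_per_new_node,
        n_hubs = n_hubs, hub_extra_degree = hub_extra_degree, seed = seed
      )
    )
    list(graph = graph, truth = truth)
  })
}

#' Generate two gene lists with a controlled overlap
#'
#' Draws two lists of exact sizes `K` and `M` from a universe of
#' `universe_N` synthetic symbols such that their intersection has exactly
#' `overlap_x` genes — the setting of the compound-target vs disease-gene
#' overlap test.
#'
#' @param universe_N Universe size.
#' @param K,M List sizes.
#' @param overlap_x Required intersection size
#'   (`overlap_x <= min(K, M)`, `K + M - overlap_x <= universe_N`).
#' @param seed RNG seed.
#' @return A list: `a`, `b` ([gene_list]s), `universe` (character vector).
#' @export
generate_target_sets <- function(universe_N, K, M, overlap_x, seed = 42) {
  stopifnot(
    overlap_x >= 0, overlap_x <= min(K, M),
    K + M - overlap_x <= universe_N
  )
  withr::with_seed(as.integer(seed), {
    universe <- filler_symbols(universe_N)
    shared <- sample_safe(universe, overlap_x)
    rest <- setdiff(universe, shared)
    a_only <- sample_safe(rest, K - overlap_x)
    b_only <- sample_safe(setdiff(rest, a_only), M - overlap_x)
    list(
      a = gene_list(c(shared, a_only), name = "compound_targets"),
      b = gene_list(c(shared, b_only), name = "disease_genes"),
      universe = universe
    )
  })
}

#' Generate Gaussian feature clouds with planted outliers
#'
#' Samples `n_clusters` spherical Gaussian clusters (unit SD) whose
#' centroids are spaced `separation` SD units apart (placed on a circle in
#' the first two feature dimensions, so the minimum pairwise centroid
#' distance equals `separation`), plus `n_outliers` rows placed
#' `outlier_distance` SD units from the global centroid mean in random
#' directions.
#'
#' @param n_per_cluster Points per cluster.
#' @param n_clusters Number of planted clusters.
#' @param separation Centroid spacing in SD units.
#' @param n_outliers Planted outlier rows.
#' @param outlier_distance Outlier distance from the global mean, SD units.
#' @param dim Feature dimension (>= 2).
#' @param seed RNG seed.
#' @return A list: `features` (tibble with `gene` ids), `truth`
#'   (`planted_outlier_rows` indices, `cluster` assignment per row,
#'   parameters).
#' @export
generate_feature_clouds <- function(n_per_cluster = 40, n_clusters = 3,
                                    separation = 6, n_outliers = 4,
                                    outlier_distance = 10, dim = 2, seed = 42) {
  stopifnot(dim >= 2, n_clusters >= 1, n_per_cluster >= 1, n_outliers >= 0)
  withr::with_seed(as.integer(seed), {
    centroids <- matrix(0, n_clusters, dim)
    if (n_clusters > 1) {
      radius <- separation / (2 * sin(pi / n_clusters))
      angles <- 2 * pi * (seq_len(n_clusters) - 1) / n_clusters
      centroids[, 1] <- radius * cos(angles)
      centroids[, 2] <- radius * sin(angles)
    }
    n_in <- n_per_cluster * n_clusters
    cluster_id <- rep(seq_len(n_clusters), each = n_per_cluster)
    X <- centroids[cluster_id, , drop = FALSE] +
      matrix(rnorm(n_in * dim), n_in, dim)
    if (n_outliers > 0) {
      centre <- colMeans(centroids)
      dirs <- matrix(rnorm(n_outliers * dim), n_outliers, dim)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      out_rows <- sweep(dirs * outlier_distance, 2, centre, "+")
      X <- rbind(X, out_rows)
      cluster_id <- c(cluster_id, rep(NA_integer_, n_outliers))
    }
    n <- nrow(X)
    colnames(X) <- paste0("f", seq_len(dim))
    features <- tibble::as_tibble(cbind(
      tibble::tibble(gene = filler_symbols(n)),
      tibble::as_tibble(X)
    ))
    truth <- list(
      planted_outlier_rows = if (n_outliers > 0) seq(n_in + 1, n) else integer(),
      cluster = cluster_id,
      params = list(
        n_per_cluster = n_per_cluster, n_clusters = n_clusters,
        separation = separation, n_outliers = n_outliers,
        outlier_distance = outlier_distance, dim = dim, seed = seed
      )
    )
    list(features = features, truth = truth)
  })
}

#' Generate a gene-set collection with planted enriched sets
#'
#' Builds `n_sets` gene sets over a universe; `n_enriched` of them draw 80%
#' of their members from `enriched_query` (so an over-representation
#' analysis of that query should rank them first), the rest are uniform
#' draws from the universe.
#'
#' @param universe A [gene_list] or character vector.
#' @param n_sets Total number of sets.
#' @param set_size_range Length-2 integer range of set sizes.
#' @param enriched_query The query list the planted sets are enriched for.
#' @param n_enriched Number of planted enriched sets.
#' @param seed RNG seed.
#' @param path Optional path; when given, the collection is also written
#'   as a GMT file.
#' @return A list: `sets` (tibble as from [read_gmt()]), `truth`
#'   (`planted_enriched_sets`), and `path` when written.
#' @export
generate_gmt <- function(universe, n_sets = 20, set_size_range = c(10, 40),
                         enriched_query, n_enriched = 3, seed = 42, path = NULL) {
  u <- unique(gene_symbols(universe))
  q <- intersect(gene_symbols(enriched_query), u)
  stopifnot(n_enriched <= n_sets, length(set_size_range) == 2)
  withr::with_seed(as.integer(seed), {
    sizes <- sample_safe(seq(set_size_range[1], set_size_range[2]), n_sets, replace = TRUE)
    enriched_names <- paste0("ENRICHED_SET", seq_len(n_enriched))
    filler_names <- paste0("SET", sprintf("%03d", seq_len(n_sets - n_enriched)))
    nm <- c(enriched_names, filler_names)
    members <- lapply(seq_len(n_sets), function(i) {
      s <- sizes[i]
      if (i <= n_enriched) {
        n_from_q <- min(length(q), round(0.8 * s))
        from_q <- sample_safe(q, n_from_q)
        from_u <- sample_safe(setdiff(u, from_q), s - n_from_q)
        c(from_q, from_u)
      } else {
        sample_safe(u, min(s, length(u)))
      }
    })
    sets <- tibble::tibble(
      set_name = nm,
      description = ifelse(seq_len(n_sets) <= n_enriched, "planted_enriched", "filler"),
      genes = members
    )
    if (!is.null(path)) write_gmt(sets, path)
    list(
      sets = sets,
      truth = list(
        planted_enriched_sets = enriched_names,
        params = list(
          n_sets = n_sets, set_size_range = set_size_range,
          n_enriched = n_enriched, seed = seed
        )
      ),
      path = path
    )
  })
}
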