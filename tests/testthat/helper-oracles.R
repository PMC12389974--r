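# Brute-force reference implementations, independent of the package's
# production code paths (no BFS-sigma accumulation, no Brandes, no dense
# matrix algebra). Used to validate every deterministic topological index
# on small graphs by explicit geodesic enumeration.

# simple adjacency representation: named list of character vectors
oracle_adj <- function(g) {
  edges <- graph_edges(g)
  nodes <- graph_nodes(g)
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) adj[[v]] <- character()
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]
    b <- edges$to[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, function(x) sort(unique(x)))
}

# single-source distances by plain frontier expansion
oracle_dist_from <- function(adj, s) {
  d <- stats::setNames(rep(NA_real_, length(adj)), names(adj))
  d[s] <- 0
  frontier <- s
  while (length(frontier) > 0) {
    nxt <- character()
    for (u in frontier) {
      for (w in adj[[u]]) {
        if (is.na(d[w])) {
          d[w] <- d[u] + 1
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- unique(nxt)
  }
  d
}

# enumerate every geodesic between s and t as a list of vertex vectors,
# by recursive backtracking over distance-decreasing neighbors
oracle_geodesics <- function(adj, d_s, s, t) {
  if (is.na(d_s[t])) return(list())
  if (s == t) return(list(s))
  walk <- function(v) {
    if (v == s) return(list(s))
    preds <- adj[[v]][!is.na(d_s[adj[[v]]]) & d_s[adj[[v]]] == d_s[v] - 1]
    out <- list()
    for (p in preds) {
      for (path in walk(p)) out <- c(out, list(c(path, v)))
    }
    out
  }
  walk(t)
}

# all deterministic indices by enumeration; returns a named list of named
# numeric vectors using the production column names
oracle_indices <- function(g) {
  adj <- oracle_adj(g)
  nodes <- names(adj)
  n <- length(nodes)
  D <- sapply(nodes, function(s) oracle_dist_from(adj, s))  # D[t, s]
  bet <- stats::setNames(numeric(n), nodes)
  stress <- stats::setNames(numeric(n), nodes)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        s <- nodes[i]
        t <- nodes[j]
        paths <- oracle_geodesics(adj, D[, s], s, t)
        if (length(paths) == 0) next
        interior <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
        cnt <- table(interior)
        stress[names(cnt)] <- stress[names(cnt)] + as.numeric(cnt)
        bet[names(cnt)] <- bet[names(cnt)] + as.numeric(cnt) / length(paths)
      }
    }
  }

  comp <- oracle_components(adj)
  comp_size <- stats::setNames(as.numeric(table(comp)[comp]), nodes)
  deg <- vapply(adj, length, numeric(1))

  closeness <- aspl <- radiality <- stats::setNames(numeric(n), nodes)
  for (v in nodes) {
    dv <- D[, v]
    reach <- names(dv)[!is.na(dv) & dv > 0]
    r <- length(reach)
    if (r == 0) next
    sumd <- sum(dv[reach])
    closeness[v] <- r / sumd
    aspl[v] <- sumd / r
    members <- nodes[comp == comp[v]]
    diam <- max(D[members, members], na.rm = TRUE)
    radiality[v] <- sum(diam + 1 - dv[reach]) / (comp_size[v] - 1)
  }

  clustering <- vapply(nodes, function(v) {
    nb <- adj[[v]]
    k <- length(nb)
    if (k < 2) return(0)
    e <- 0
    for (a in nb) e <- e + sum(adj[[a]] %in% nb)
    (e / 2) * 2 / (k * (k - 1))
  }, numeric(1))

  neigh_conn <- vapply(nodes, function(v) {
    nb <- adj[[v]]
    if (length(nb) == 0) return(0)
    mean(deg[nb])
  }, numeric(1))

  tc <- vapply(nodes, function(v) {
    k <- length(adj[[v]])
    if (k < 1) return(0)
    vals <- c()
    for (w in setdiff(nodes, v)) {
      shared <- length(intersect(adj[[v]], adj[[w]]))
      if (shared >= 1) {
        vals <- c(vals, (shared + (w %in% adj[[v]])) / k)
      }
    }
    if (length(vals) == 0) 0 else mean(vals)
  }, numeric(1))

  mnc <- vapply(nodes, function(v) {
    nb <- adj[[v]]
    if (length(nb) == 0) return(0)
    sub <- lapply(stats::setNames(nb, nb), function(u) intersect(adj[[u]], nb))
    max(as.numeric(table(oracle_components(sub))))
  }, numeric(1))

  bottleneck <- oracle_bottleneck(adj, D, comp, comp_size)

  list(
    MNC = mnc,
    Bottleneck = bottleneck,
    BetweennessCentrality = ifelse(
      comp_size >= 3, bet * 2 / ((comp_size - 1) * (comp_size - 2)), 0
    ),
    ClosenessCentrality = closeness,
    Degree = deg,
    Radiality = radiality,
    Stress = stress,
    AverageShortestPathLength = aspl,
    ClusteringCoefficient = clustering,
    NeighborhoodConnectivity = neigh_conn,
    TopologicalCoefficient = tc,
    NumberOfUndirectedEdges = deg,
    Betweenness = bet
  )
}

oracle_components <- function(adj) {
  nodes <- names(adj)
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  cur <- 0L
  for (s in nodes) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier) > 0) {
      nxt <- character()
      for (u in frontier) {
        for (w in adj[[u]]) {
          if (is.na(comp[w])) {
            comp[w] <- cur
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  comp
}

# independent bottleneck: explicit tree construction per root, children
# lists, recursive subtree counting; parent = lexicographically smallest
# predecessor
oracle_bottleneck <- function(adj, D, comp, comp_size) {
  nodes <- names(adj)
  res <- stats::setNames(numeric(length(nodes)), nodes)
  for (s in nodes) {
    ds <- D[, s]
    members <- nodes[!is.na(ds)]
    parent <- stats::setNames(rep(NA_character_, length(members)), members)
    for (w in setdiff(members, s)) {
      preds <- adj[[w]][!is.na(ds[adj[[w]]]) & ds[adj[[w]]] == ds[w] - 1]
      parent[w] <- sort(preds, method = "radix")[1]
    }
    subtree_size <- function(v) {
      kids <- members[!is.na(parent[members]) & parent[members] == v]
      1 + sum(vapply(kids, subtree_size, numeric(1)))
    }
    for (v in setdiff(members, s)) {
      if (subtree_size(v) > comp_size[s] / 4) res[v] <- res[v] + 1
    }
  }
  res
}

# seeded Erdos-Renyi style random graph over letter symbols; resamples
# until at least one edge survives cleaning
random_test_graph <- function(n, p, seed) {
  set.seed(seed)
  repeat {
    pairs <- t(combn(n, 2))
    keep <- runif(nrow(pairs)) < p
    if (!any(keep)) next
    syms <- sprintf("N%02d", seq_len(n))
    return(as_ppi_graph(data.frame(
      from = syms[pairs[keep, 1]],
      to = syms[pairs[keep, 2]]
    )))
  }
}

# compare every deterministic index against the oracle
expect_matches_oracle <- function(g, tol = 1e-9) {
  ct <- centrality_table(g, epc_iterations = 5, seed = 1)
  oracle <- oracle_indices(g)
  for (idx in setdiff(centrality_columns(), "EPC")) {
    expect_equal(
      stats::setNames(ct[[idx]], ct$gene),
      oracle[[idx]][ct$gene],
      tolerance = tol, info = idx
    )
  }
}

# Wilcoxon/Mann-Whitney AUC of a score against binary truth
score_auc <- function(score, truth) {
  r <- rank(score)
  n1 <- sum(truth)
  n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# small hand fixtures used across test files
fixture_p3 <- function() as_ppi_graph(data.frame(a = c("A", "B"), b = c("B", "C")))
fixture_c4 <- function() {
  as_ppi_graph(data.frame(a = c("A", "B", "C", "D"), b = c("B", "C", "D", "A")))
}
fixture_star4 <- function() {
  as_ppi_graph(data.frame(a = rep("C0", 4), b = paste0("L", 1:4)))
}
fixture_k13 <- function() {
  as_ppi_graph(data.frame(a = rep("C0", 3), b = paste0("L", 1:3)))
}
fixture_p5 <- function() {
  as_ppi_graph(data.frame(a = c("A", "B", "C", "D"), b = c("B", "C", "D", "E")))
}
fixture_triangle <- function() {
  as_ppi_graph(data.frame(a = c("A", "B", "C"), b = c("B", "C", "A")))
}
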