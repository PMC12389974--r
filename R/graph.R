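#' Build a PPI graph from an edge table
#'
#' Constructs an undirected simple graph over gene symbols from a data frame
#' whose first two columns name the interacting partners. Symbols are
#' upper-cased, self-loops are dropped, duplicate pairs (in either
#' orientation) are collapsed, and — by default — nodes left without any
#' edge are removed, mirroring the usual treatment of hidden disconnected
#' nodes in PPI network viewers.
#'
#' @param edges A data frame (or tibble) whose first two columns are gene
#'   symbols; extra columns are ignored.
#' @param keep_isolated Keep nodes that end up with no incident edge after
#'   cleaning? Only relevant when `nodes` supplies extra symbols.
#' @param nodes Optional character vector of node symbols to include in
#'   addition to edge endpoints (isolated unless `keep_isolated = FALSE`).
#'
#' @return A `ppi_graph` object: node set (lexicographic order), edge matrix
#'   and adjacency lists. Convert back to a tibble of edges with
#'   [graph_edges()].
#' @examples
#' g <- as_ppi_graph(data.frame(a = c("tp53", "TNF"), b = c("TNF", "EGFR")))
#' graph_nodes(g)
#' @export
as_ppi_graph <- function(edges, keep_isolated = FALSE, nodes = NULL) {
  if (!is.data.frame(edges) || ncol(edges) < 2) {
    abort("`edges` must be a data frame with at least two columns of gene symbols.")
  }
  from <- normalize_symbols(edges[[1]])
  to <- normalize_symbols(edges[[2]])
  keep <- !is.na(from) & !is.na(to) & from != "" & to != ""
  from <- from[keep]
  to <- to[keep]
  new_ppi_graph(from, to,
    extra_nodes = normalize_symbols(nodes %||% character()),
    keep_isolated = keep_isolated
  )
}

# Core constructor used by readers and generators; endpoints already
# normalized. Enforces the graph invariants (no self-loops, no duplicate
# edges, symmetric adjacency).
new_ppi_graph <- function(from, to, extra_nodes = character(), keep_isolated = FALSE) {
  loop <- from == to
  from <- from[!loop]
  to <- to[!loop]
  a <- pmin(from, to)
  b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  a <- a[!dup]
  b <- b[!dup]

  node_names <- sort_c(unique(c(a, b, if (keep_isolated) extra_nodes)))
  n <- length(node_names)
  if (n == 0L) {
    abort("Graph is empty after cleaning (no valid edges remain).",
      class = "netprio_empty_graph"
    )
  }
  ia <- match(a, node_names)
  ib <- match(b, node_names)
  edge_mat <- cbind(pmin(ia, ib), pmax(ia, ib))
  if (nrow(edge_mat) > 0L) {
    o <- order(edge_mat[, 1], edge_mat[, 2])
    edge_mat <- edge_mat[o, , drop = FALSE]
  }
  adj <- rep(list(integer()), n)
  if (nrow(edge_mat) > 0L) {
    nb <- split(c(edge_mat[, 2], edge_mat[, 1]), c(edge_mat[, 1], edge_mat[, 2]))
    idx <- as.integer(names(nb))
    adj[idx] <- lapply(nb, function(v) sort(as.integer(v)))
  }
  structure(
    list(nodes = node_names, edges = edge_mat, adj = adj),
    class = "ppi_graph"
  )
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat(sprintf(
    "<ppi_graph> %d nodes, %d edges\n",
    length(x$nodes), nrow(x$edges)
  ))
  shown <- head(x$nodes, 8)
  cat("  nodes: ", paste(shown, collapse = ", "),
    if (length(x$nodes) > 8) ", ..." else "", "\n",
    sep = ""
  )
  invisible(x)
}

#' Graph accessors
#'
#' `graph_nodes()` returns the node symbols (lexicographic order);
#' `graph_edges()` the edge list as a two-column tibble; `n_nodes()` /
#' `n_edges()` the corresponding counts.
#'
#' @param g A `ppi_graph`.
#' @return A character vector, tibble, or integer count.
#' @export
graph_nodes <- function(g) {
  stopifnot(inherits(g, "ppi_graph"))
  g$nodes
}

#' @rdname graph_nodes
#' @export
graph_edges <- function(g) {
  stopifnot(inherits(g, "ppi_graph"))
  tibble::tibble(
    from = g$nodes[g$edges[, 1]],
    to = g$nodes[g$edges[, 2]]
  )
}

#' @rdname graph_nodes
#' @export
n_nodes <- function(g) length(graph_nodes(g))

#' @rdname graph_nodes
#' @export
n_edges <- function(g) {
  stopifnot(inherits(g, "ppi_graph"))
  nrow(g$edges)
}

# Resolve node symbols to indices, with a lookup error for unknown genes.
node_index <- function(g, v) {
  idx <- match(normalize_symbols(v), g$nodes)
  if (anyNA(idx)) {
    abort(
      sprintf(
        "Unknown node(s): %s",
        paste(v[is.na(idx)], collapse = ", ")
      ),
      class = "netprio_unknown_node"
    )
  }
  idx
}

# Connected-component membership (integer labels) and sizes.
graph_components <- function(g) {
  n <- length(g$nodes)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0L) {
      u <- queue[[1]]
      queue <- queue[-1]
      nb <- g$adj[[u]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

# Dense adjacency matrix (logical) — fine at the network sizes this
# pipeline targets (hundreds to low thousands of nodes).
adjacency_matrix <- function(g) {
  n <- length(g$nodes)
  A <- matrix(0, n, n, dimnames = list(g$nodes, g$nodes))
  if (nrow(g$edges) > 0) {
    A[g$edges] <- 1
    A[g$edges[, c(2, 1), drop = FALSE]] <- 1
  }
  A
}
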