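#' Read a STRING-style interaction export
#'
#' Parses a tab-separated STRING network export (columns
#' `protein1`/`protein2`/`combined_score`, or the `node1`/`node2`/`score`
#' dialect written by the web interface, with or without a leading `#`),
#' applies the confidence filter, and returns a cleaned [ppi_graph][as_ppi_graph].
#'
#' The confidence threshold is expressed on the 0-1 scale (0.4 = "medium
#' confidence"). STRING files that carry scores on the native 0-1000 integer
#' scale are rescaled by 1/1000 before comparison. Edges below the
#' threshold, self-loops and duplicate pairs are discarded; nodes left
#' disconnected are removed unless `keep_isolated = TRUE`.
#'
#' @param path Path to the TSV export.
#' @param min_score Minimum combined confidence score on the 0-1 scale;
#'   edges with score `>= min_score` are kept. Default 0.4.
#' @param keep_isolated Keep nodes that lose all their edges to the filter?
#' @return A `ppi_graph`.
#' @export
read_string_tsv <- function(path, min_score = 0.4, keep_isolated = FALSE) {
  if (!is.numeric(min_score) || length(min_score) != 1 || min_score < 0 || min_score > 1) {
    abort("`min_score` must be a single number in [0, 1].")
  }
  df <- readr::read_tsv(path,
    show_col_types = FALSE, progress = FALSE,
    comment = "", name_repair = "minimal"
  )
  nm <- tolower(sub("^#", "", names(df)))
  names(df) <- nm
  node_cols <- intersect(c("protein1", "protein2", "node1", "node2"), nm)
  score_col <- intersect(c("combined_score", "score"), nm)
  c1 <- intersect(c("protein1", "node1"), nm)[1]
  c2 <- intersect(c("protein2", "node2"), nm)[1]
  if (is.na(c1) || is.na(c2) || length(score_col) == 0) {
    abort(
      paste0(
        "Not a STRING-style export: need two node columns ",
        "(protein1/protein2 or node1/node2) and a combined_score/score column; found: ",
        paste(names(df), collapse = ", ")
      ),
      class = "netprio_format_error"
    )
  }
  score <- as.numeric(df[[score_col[1]]])
  # native STRING exports score 0-1000; rescale to [0,1] when needed
  if (any(score > 1, na.rm = TRUE)) score <- score / 1000
  keep <- !is.na(score) & score >= min_score
  from <- normalize_symbols(df[[c1]])[keep]
  to <- normalize_symbols(df[[c2]])[keep]
  if (length(from) == 0L) {
    abort("No edges pass the confidence filter: the network is empty.",
      class = "netprio_empty_graph"
    )
  }
  all_nodes <- unique(normalize_symbols(c(df[[c1]], df[[c2]])))
  new_ppi_graph(from, to, extra_nodes = all_nodes, keep_isolated = keep_isolated)
}

#' Read a plain two-column edge list
#'
#' Whitespace- or tab-separated pairs of gene symbols, one edge per line;
#' lines starting with `#` and blank lines are ignored. The same cleaning
#' rules as [read_string_tsv()] apply, minus the score filter.
#'
#' @inheritParams read_string_tsv
#' @return A `ppi_graph`.
#' @export
read_edge_list <- function(path, keep_isolated = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  content <- !grepl("^\\s*(#|$)", lines)
  idx <- which(content)
  fields <- strsplit(trimws(lines[content]), "\\s+")
  bad <- which(vapply(fields, length, integer(1)) != 2L)
  if (length(bad) > 0) {
    abort(
      sprintf(
        "Edge list line %d does not have exactly 2 fields: '%s'",
        idx[bad[1]], lines[idx[bad[1]]]
      ),
      class = "netprio_format_error"
    )
  }
  if (length(fields) == 0L) {
    abort("Edge list contains no edges.", class = "netprio_empty_graph")
  }
  from <- normalize_symbols(vapply(fields, `[[`, character(1), 1))
  to <- normalize_symbols(vapply(fields, `[[`, character(1), 2))
  new_ppi_graph(from, to,
    extra_nodes = unique(c(from, to)),
    keep_isolated = keep_isolated
  )
}

#' Gene lists
#'
#' A named, ordered, deduplicated set of gene symbols. Symbols are
#' upper-cased; duplicates (case-insensitive) keep their first position.
#'
#' @param symbols Character vector of gene symbols.
#' @param name Label for the list.
#' @return A `gene_list`.
#' @examples
#' gene_list(c("TP53", "tnf", "TP53"), name = "targets")
#' @export
gene_list <- function(symbols, name = "gene_list") {
  s <- normalize_symbols(symbols)
  s <- s[!is.na(s) & s != ""]
  s <- s[!duplicated(s)]
  structure(list(name = name, symbols = s), class = "gene_list")
}

#' @export
print.gene_list <- function(x, ...) {
  cat(sprintf("<gene_list> '%s': %d symbols\n", x$name, length(x$symbols)))
  shown <- head(x$symbols, 10)
  cat("  ", paste(shown, collapse = ", "),
    if (length(x$symbols) > 10) ", ..." else "", "\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname gene_list
#' @param x A `gene_list`.
#' @export
gene_symbols <- function(x) {
  if (inherits(x, "gene_list")) x$symbols else normalize_symbols(x)
}

#' @export
length.gene_list <- function(x) length(x$symbols)

#' Read / write one-symbol-per-line gene lists
#'
#' @param path File with one gene symbol per line (CRLF tolerated).
#' @param name Label for the list; defaults to the file name.
#' @return `read_gene_list()`: a [gene_list]; `write_gene_list()`: the path,
#'   invisibly.
#' @export
read_gene_list <- function(path, name = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("\r$", "", lines))
  lines <- lines[lines != ""]
  if (length(lines) == 0L) {
    warn(sprintf("Gene list '%s' is empty.", path))
  }
  gene_list(lines, name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname read_gene_list
#' @param genes A `gene_list` or character vector.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(gene_symbols(genes), path)
  invisible(path)
}

#' Write a result table as CSV
#'
#' Emits a header row and a deterministic row order: if the table has a
#' `composite_rank` column rows are ordered by it, otherwise
#' lexicographically by the first character column.
#'
#' @param table A data frame.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  if ("composite_rank" %in% names(table)) {
    table <- table[order(table$composite_rank, table[[1]], method = "radix"), , drop = FALSE]
  } else if (ncol(table) > 0 && is.character(table[[1]])) {
    table <- table[order(table[[1]], method = "radix"), , drop = FALSE]
  }
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}
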