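# Exact hypergeometric overlap testing and generic gene-set
# over-representation analysis.

#' Upper-tail hypergeometric probability
#'
#' Probability of observing at least `x` successes when drawing `K` items
#' without replacement from a universe of `N` items of which `M` are
#' successes:
#' `P(X >= x) = sum_{j=x}^{min(K,M)} C(M,j) C(N-M,K-j) / C(N,K)`.
#' Evaluated in log space through log-gamma terms, so it stays accurate for
#' genome-scale universes (N ~ 2e4) and astronomically small tails.
#'
#' @param N Universe size.
#' @param K Number of draws (e.g. size of the first gene list).
#' @param M Number of successes in the universe (size of the second list).
#' @param x Observed overlap.
#' @param log Return the natural-log probability? Default TRUE (the value
#'   is stored on the log scale; `x > min(K, M)` gives `-Inf`, i.e. an
#'   exact zero tail).
#' @return Log probability (or probability when `log = FALSE`).
#' @examples
#' exp(hypergeom_tail(10, 5, 4, 4)) # 1/42
#' @export
hypergeom_tail <- function(N, K, M, x, log = TRUE) {
  stopifnot(
    length(N) == 1, length(K) == 1, length(M) == 1, length(x) == 1,
    N >= 0, K >= 0, M >= 0, K <= N, M <= N
  )
  x <- max(0, as.numeric(x))
  hi <- min(K, M)
  if (x > hi) {
    return(if (log) -Inf else 0)
  }
  j <- seq(x, hi)
  j <- j[K - j <= N - M] # impossible terms excluded
  terms <- lchoose(M, j) + lchoose(N - M, K - j) - lchoose(N, K)
  lp <- min(logsumexp(terms), 0)
  if (log) lp else exp(lp)
}

#' Hypergeometric test of gene-list overlap
#'
#' Tests whether the observed intersection of two gene lists exceeds what
#' random draws from a common universe of `universe_N` annotated genes
#' would produce (one-sided, over-representation). Symbols are
#' case-normalized before intersecting.
#'
#' @param a,b [gene_list]s or character vectors of gene symbols.
#' @param universe_N Size of the annotated universe both lists were drawn
#'   from; must be supplied explicitly and be at least `|a union b|`.
#' @return An `overlap_test` object with fields `universe_N`, `draws_K`,
#'   `successes_M`, `observed_x`, `expected`, `log_p`, `p_value`. Has
#'   [tidy()] and [glance()] methods.
#' @examples
#' overlap_test(c("TP53", "TNF", "EGFR"), c("TP53", "TNF", "INS"), universe_N = 100)
#' @export
overlap_test <- function(a, b, universe_N) {
  sa <- gene_symbols(a)
  sb <- gene_symbols(b)
  union_n <- length(union(sa, sb))
  if (!is.numeric(universe_N) || length(universe_N) != 1 || universe_N < union_n) {
    abort(sprintf(
      "`universe_N` must be a single number >= |union(a, b)| = %d.",
      union_n
    ))
  }
  x <- length(intersect(sa, sb))
  K <- length(sa)
  M <- length(sb)
  lp <- hypergeom_tail(universe_N, K, M, x, log = TRUE)
  structure(
    list(
      universe_N = universe_N,
      draws_K = K,
      successes_M = M,
      observed_x = x,
      expected = K * M / universe_N,
      log_p = lp,
      p_value = exp(lp)
    ),
    class = "overlap_test"
  )
}

#' @export
print.overlap_test <- function(x, ...) {
  cat("Hypergeometric overlap test (one-sided, over-representation)\n")
  cat(sprintf(
    "  N = %d, K = %d, M = %d; observed overlap x = %d (expected %.1f)\n",
    x$universe_N, x$draws_K, x$successes_M, x$observed_x, x$expected
  ))
  cat(sprintf(
    "  P(X >= x) = %.4g  (log10 p = %.2f)\n",
    x$p_value, x$log_p / log(10)
  ))
  invisible(x)
}

#' @rdname overlap_test
#' @param x An `overlap_test`.
#' @param ... Unused.
#' @method tidy overlap_test
#' @export
tidy.overlap_test <- function(x, ...) {
  tibble::tibble(
    universe_N = x$universe_N, draws_K = x$draws_K,
    successes_M = x$successes_M, observed_x = x$observed_x,
    expected = x$expected, log10_p = x$log_p / log(10), p_value = x$p_value
  )
}

#' @rdname overlap_test
#' @method glance overlap_test
#' @export
glance.overlap_test <- tidy.overlap_test

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()]), returned in the original order and capped at 1.
#'
#' @param pvals Numeric vector of p-values.
#' @return Adjusted values, same order.
#' @export
bh_adjust <- function(pvals) {
  p.adjust(pvals, method = "BH")
}

#' Read / write GMT gene-set collections
#'
#' GMT is tab-separated: set name, description, then member genes. The
#' reader returns a tibble with a list-column of members (symbols
#' upper-cased, deduplicated).
#'
#' @param path GMT file path.
#' @return `read_gmt()`: tibble with columns `set_name`, `description`,
#'   `genes` (list-column); `write_gmt()`: the path, invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[trimws(lines) != ""]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 3L)
  if (length(bad) > 0) {
    abort(sprintf("GMT line %d has fewer than 3 tab-separated fields.", bad[1]),
      class = "netprio_format_error"
    )
  }
  tibble::tibble(
    set_name = vapply(parts, `[[`, character(1), 1),
    description = vapply(parts, `[[`, character(1), 2),
    genes = lapply(parts, function(p) unique(normalize_symbols(p[-c(1, 2)])))
  )
}

#' @rdname read_gmt
#' @param sets Named list of character vectors, or a tibble as returned by
#'   `read_gmt()`.
#' @export
write_gmt <- function(sets, path) {
  if (is.data.frame(sets)) {
    nm <- sets$set_name
    desc <- if ("description" %in% names(sets)) sets$description else rep("na", nrow(sets))
    members <- sets$genes
  } else {
    nm <- names(sets)
    desc <- rep("na", length(sets))
    members <- sets
  }
  lines <- vapply(seq_along(nm), function(i) {
    paste(c(nm[i], desc[i], members[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation analysis against a gene-set collection
#'
#' One upper-tail hypergeometric test per gene set, restricted to the
#' supplied universe, with Benjamini-Hochberg FDR across all tested sets.
#' Query genes outside the universe are dropped with a warning.
#'
#' @param query A [gene_list] or character vector of genes of interest.
#' @param collection Gene sets: a tibble from [read_gmt()] or a named list
#'   of character vectors.
#' @param universe A [gene_list] or character vector defining the testable
#'   universe.
#' @return A tibble sorted by ascending p-value: `set_name`, `set_size`
#'   (members within the universe), `overlap_count`, `p_value`, `bh_fdr`.
#' @export
ora_enrich <- function(query, collection, universe) {
  q <- gene_symbols(query)
  u <- unique(gene_symbols(universe))
  outside <- setdiff(q, u)
  if (length(outside) > 0) {
    warn(sprintf(
      "%d query gene(s) outside the universe dropped: %s%s",
      length(outside), paste(head(outside, 5), collapse = ", "),
      if (length(outside) > 5) ", ..." else ""
    ))
    q <- intersect(q, u)
  }
  if (is.data.frame(collection)) {
    sets <- stats::setNames(collection$genes, collection$set_name)
  } else {
    sets <- collection
  }
  if (length(sets) == 0) {
    warn("Empty gene-set collection; returning no enrichment rows.")
    return(tibble::tibble(
      set_name = character(), set_size = integer(),
      overlap_count = integer(), p_value = numeric(), bh_fdr = numeric()
    ))
  }
  N <- length(u)
  K <- length(q)
  rows <- purrr::map(names(sets), function(nm) {
    members <- intersect(unique(normalize_symbols(sets[[nm]])), u)
    x <- length(intersect(q, members))
    tibble::tibble(
      set_name = nm,
      set_size = length(members),
      overlap_count = x,
      p_value = hypergeom_tail(N, K, length(members), x, log = FALSE)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$bh_fdr <- bh_adjust(out$p_value)
  dplyr::arrange(out, .data$p_value, .data$set_name)
}
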