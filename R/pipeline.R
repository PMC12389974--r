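# End-to-end orchestration: config, staged execution with logging,
# reproducibility manifest, and a regenerable text report.

#' Run configuration
#'
#' Collects every tunable of the pipeline with its default. Defaults follow
#' the reference workflow: STRING confidence 0.4, K-means `max_iter` 300 /
#' `tol` 1e-4 over k = 1..10, Isolation Forest with 100 trees, 0.8
#' subsampling and contamination 0.10, two PCA components, core-gene rank
#' threshold 20, seed 42. The hub panel (MNC, EPC, Bottleneck, Betweenness)
#' and its `hub_top_k` control which genes enter the machine-learning
#' stage; `hub_top_k = NULL` skips the hub restriction and prioritizes all
#' network genes.
#'
#' @param network_file Path to the network (STRING TSV or plain edge list).
#' @param network_format `"string"` or `"edgelist"`.
#' @param targets_file,disease_file Optional gene-list paths for the
#'   overlap test.
#' @param gmt_file Optional GMT collection for enrichment.
#' @param universe_N Annotated-universe size for the overlap test
#'   (required when both gene lists are given; no default on purpose).
#' @param string_min_score Confidence threshold on the 0-1 scale.
#' @param epc_retain_p,epc_iterations EPC Monte-Carlo parameters.
#' @param hub_metrics,hub_top_k Hub-intersection panel and per-metric
#'   depth.
#' @param descending_indices,ascending_indices Rank direction partition.
#' @param k_range,kmeans_max_iter,kmeans_tol K-means/elbow controls.
#' @param n_trees,subsample_fraction,contamination Isolation Forest
#'   controls.
#' @param n_components Retained principal components.
#' @param rank_threshold Core-gene composite-rank cutoff.
#' @param feature_missing_max,sample_missing_max Missing-value policy.
#' @param keep_isolated Keep isolated nodes at network read time.
#' @param seed Master seed; every stage derives its own substream.
#' @return A validated `run_config` list.
#' @export
run_config <- function(network_file = NULL,
                       network_format = c("string", "edgelist"),
                       targets_file = NULL,
                       disease_file = NULL,
                       gmt_file = NULL,
                       universe_N = NULL,
                       string_min_score = 0.4,
                       epc_retain_p = 0.5,
                       epc_iterations = 1000,
                       hub_metrics = c("MNC", "EPC", "Bottleneck", "Betweenness"),
                       hub_top_k = 30,
                       descending_indices = default_descending_indices(),
                       ascending_indices = default_ascending_indices(),
                       k_range = 1:10,
                       kmeans_max_iter = 300,
                       kmeans_tol = 1e-4,
                       n_trees = 100,
                       subsample_fraction = 0.8,
                       contamination = 0.10,
                       n_components = 2,
                       rank_threshold = 20,
                       feature_missing_max = 0.005,
                       sample_missing_max = 0.005,
                       keep_isolated = FALSE,
                       seed = 42) {
  network_format <- match.arg(network_format)
  if (length(intersect(descending_indices, ascending_indices)) > 0 ||
    !setequal(c(descending_indices, ascending_indices), centrality_columns())) {
    abort(
      "Direction sets must be disjoint and together cover all 14 centrality columns.",
      class = "netprio_config_error"
    )
  }
  if (!is.null(hub_top_k)) {
    stopifnot(hub_top_k >= 1)
    missing_m <- setdiff(hub_metrics, centrality_columns())
    if (length(missing_m) > 0) {
      abort(sprintf("Unknown hub metrics: %s", paste(missing_m, collapse = ", ")),
        class = "netprio_config_error"
      )
    }
  }
  structure(
    list(
      network_file = network_file, network_format = network_format,
      targets_file = targets_file, disease_file = disease_file,
      gmt_file = gmt_file, universe_N = universe_N,
      string_min_score = string_min_score,
      epc_retain_p = epc_retain_p, epc_iterations = epc_iterations,
      hub_metrics = hub_metrics, hub_top_k = hub_top_k,
      descending_indices = descending_indices,
      ascending_indices = ascending_indices,
      k_range = k_range, kmeans_max_iter = kmeans_max_iter,
      kmeans_tol = kmeans_tol, n_trees = n_trees,
      subsample_fraction = subsample_fraction,
      contamination = contamination, n_components = n_components,
      rank_threshold = rank_threshold,
      feature_missing_max = feature_missing_max,
      sample_missing_max = sample_missing_max,
      keep_isolated = keep_isolated,
      seed = seed
    ),
    class = "run_config"
  )
}

#' Run the full prioritization pipeline
#'
#' Executes the staged analysis — read network, centrality table, hub
#' intersection, feature cleaning/standardization, elbow K-means +
#' Isolation Forest + PCA, composite scoring, core-gene selection, and
#' (when gene lists are configured) the overlap test and optional
#' enrichment — writing each stage's table plus a reproducibility manifest
#' to `out_dir`. A failing stage aborts with the stage name; outputs
#' already written are renamed with a `.partial` suffix.
#'
#' @param config A [run_config]; paths in it may be overridden by `graph`.
#' @param out_dir Output directory (created if needed).
#' @param graph Optionally, a prebuilt [ppi_graph][as_ppi_graph] used
#'   instead of reading `config$network_file`.
#' @param quiet Suppress stage log messages?
#' @return Invisibly, a list with the key results: `centrality`, `hubs`,
#'   `prioritization` (a `target_prioritization`), `core_genes`, `overlap`,
#'   `enrichment`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir, graph = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  log_stage <- function(...) if (!quiet) message(sprintf(...))
  counts <- list()
  emit <- function(obj, file, writer = write_table) {
    p <- file.path(out_dir, file)
    writer(obj, p)
    written <<- c(written, p)
    p
  }
  current_stage <- "init"
  result <- tryCatch(
    {
      current_stage <- "read_network"
      g <- graph %||% switch(config$network_format,
        string = read_string_tsv(config$network_file,
          min_score = config$string_min_score,
          keep_isolated = config$keep_isolated
        ),
        edgelist = read_edge_list(config$network_file,
          keep_isolated = config$keep_isolated
        )
      )
      counts$nodes <- n_nodes(g)
      counts$edges <- n_edges(g)
      log_stage("[read_network] %d nodes, %d edges", counts$nodes, counts$edges)

      current_stage <- "centrality"
      ct <- centrality_table(g,
        epc_retain_p = config$epc_retain_p,
        epc_iterations = config$epc_iterations,
        seed = stage_seed(config$seed, "epc")
      )
      emit(ct, "centrality.csv")
      log_stage("[centrality] %d genes x %d indices", nrow(ct), ncol(ct) - 1)

      current_stage <- "hub_intersection"
      if (!is.null(config$hub_top_k)) {
        hubs <- hub_intersection(ct,
          metrics = config$hub_metrics,
          top_k = min(config$hub_top_k, nrow(ct))
        )
        features <- ct[ct$gene %in% gene_symbols(hubs), , drop = FALSE]
      } else {
        hubs <- gene_list(ct$gene, name = "all_genes")
        features <- ct
      }
      emit(hubs, "hubs.txt", write_gene_list)
      counts$hubs <- length(gene_symbols(hubs))
      log_stage("[hub_intersection] %d intersecting hub genes", counts$hubs)
      if (counts$hubs < 3) {
        abort("Fewer than 3 hub genes; prioritization needs more rows (raise hub_top_k).")
      }

      current_stage <- "prioritize"
      pr <- prioritize_targets(features,
        descending_indices = config$descending_indices,
        ascending_indices = config$ascending_indices,
        k_range = config$k_range,
        n_trees = config$n_trees,
        subsample_fraction = config$subsample_fraction,
        contamination = config$contamination,
        rank_threshold = config$rank_threshold,
        feature_missing_max = config$feature_missing_max,
        sample_missing_max = config$sample_missing_max,
        max_iter = config$kmeans_max_iter,
        tol = config$kmeans_tol,
        seed = stage_seed(config$seed, "prioritize")
      )
      emit(tidy(pr), "prioritization.csv")
      emit(pr$elbow$wcss, "wcss.csv")
      counts$chosen_k <- pr$elbow$chosen_k
      counts$outliers <- sum(pr$table$is_outlier)
      log_stage(
        "[prioritize] k = %d, %d outliers flagged",
        counts$chosen_k, counts$outliers
      )

      current_stage <- "core_genes"
      core <- select_core_genes(pr, rank_threshold = config$rank_threshold)
      emit(core, "core_genes.txt", write_gene_list)
      counts$core <- length(gene_symbols(core))
      log_stage("[core_genes] %d core genes", counts$core)

      current_stage <- "overlap_test"
      overlap <- NULL
      if (!is.null(config$targets_file) && !is.null(config$disease_file)) {
        if (is.null(config$universe_N)) {
          abort("`universe_N` is required for the overlap test and has no default.")
        }
        ta <- read_gene_list(config$targets_file)
        tb <- read_gene_list(config$disease_file)
        overlap <- overlap_test(ta, tb, universe_N = config$universe_N)
        emit(
          tidy(overlap), "overlap.json",
          function(obj, p) {
            jsonlite::write_json(as.list(obj), p,
              auto_unbox = TRUE, digits = NA
            )
          }
        )
        counts$overlap_x <- overlap$observed_x
        log_stage(
          "[overlap_test] x = %d, log10 p = %.2f",
          overlap$observed_x, overlap$log_p / log(10)
        )
      }

      current_stage <- "enrichment"
      enrichment <- NULL
      if (!is.null(config$gmt_file) && !is.null(overlap)) {
        collection <- read_gmt(config$gmt_file)
        ta <- read_gene_list(config$targets_file)
        enrichment <- ora_enrich(gene_symbols(core), collection,
          universe = unique(c(
            unlist(collection$genes), gene_symbols(ta), gene_symbols(core)
          ))
        )
        emit(enrichment, "enrichment.csv")
        log_stage("[enrichment] %d sets tested", nrow(enrichment))
      }

      current_stage <- "manifest"
      manifest <- build_manifest(config, counts)
      emit(
        manifest, "manifest.json",
        function(obj, p) jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA)
      )

      list(
        centrality = ct, hubs = hubs, prioritization = pr,
        core_genes = core, overlap = overlap, enrichment = enrichment,
        manifest = manifest, out_dir = out_dir
      )
    },
    error = function(e) {
      for (p in written) {
        if (file.exists(p)) file.rename(p, paste0(p, ".partial"))
      }
      abort(
        sprintf("Pipeline stage '%s' failed: %s", current_stage, conditionMessage(e)),
        class = "netprio_pipeline_error",
        parent = e
      )
    }
  )
  invisible(result)
}

build_manifest <- function(config, counts) {
  inputs <- list()
  for (f in c("network_file", "targets_file", "disease_file", "gmt_file")) {
    p <- config[[f]]
    if (!is.null(p) && file.exists(p)) {
      inputs[[f]] <- list(path = p, md5 = unname(tools::md5sum(p)))
    }
  }
  cfg <- unclass(config)
  cfg$k_range <- paste(range(cfg$k_range), collapse = ":")
  list(
    tool = "netprio",
    version = as.character(utils::packageVersion("netprio")),
    config = cfg,
    inputs = inputs,
    stage_counts = counts,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}

#' Summarize a finished pipeline run
#'
#' Rebuilds a human-readable summary purely from the tables a
#' [run_pipeline()] call saved: overlap test, chosen cluster number,
#' flagged outliers, the top composite table (columns `Gene`,
#' `Composite Score`) and the core-gene list.
#'
#' @param out_dir Directory written by [run_pipeline()].
#' @param top_n Rows of the composite table to show. Default 10.
#' @return The report lines, invisibly; printed to the console.
#' @export
report_run <- function(out_dir, top_n = 10) {
  lines <- character()
  push <- function(...) lines <<- c(lines, sprintf(...))
  push("netprio run report: %s", out_dir)

  overlap_path <- file.path(out_dir, "overlap.json")
  if (file.exists(overlap_path)) {
    ov <- jsonlite::read_json(overlap_path, simplifyVector = TRUE)
    push(
      "Overlap test: x = %d of K = %d vs M = %d in N = %d (expected %.1f), log10 p = %.2f",
      ov$observed_x, ov$draws_K, ov$successes_M, ov$universe_N,
      ov$expected, ov$log10_p
    )
  }

  pr_path <- file.path(out_dir, "prioritization.csv")
  if (file.exists(pr_path)) {
    pr <- readr::read_csv(pr_path, show_col_types = FALSE, progress = FALSE)
    manifest <- jsonlite::read_json(file.path(out_dir, "manifest.json"))
    push("Clusters: k = %s", manifest$stage_counts$chosen_k)
    push(
      "Outliers flagged: %d of %d genes",
      sum(pr$is_outlier), nrow(pr)
    )
    push("Top %d genes by composite score:", min(top_n, nrow(pr)))
    push("  %-12s %s", "Gene", "Composite Score")
    top <- head(pr[order(pr$composite_rank), ], top_n)
    for (i in seq_len(nrow(top))) {
      push("  %-12s %.2f", top$gene[i], top$composite_score[i])
    }
  }

  core_path <- file.path(out_dir, "core_genes.txt")
  if (file.exists(core_path)) {
    core <- readLines(core_path, warn = FALSE)
    core <- core[core != ""]
    if (length(core) == 0) {
      push("Core genes: none selected (empty set)")
    } else {
      push("Core genes (%d): %s", length(core), paste(core, collapse = ", "))
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
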