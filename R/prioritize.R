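# Machine-learning prioritization workflow: feature cleaning and
# standardization, K-means with elbow selection, Isolation Forest,
# 2D PCA projection, direction-aware rank aggregation, core-gene rule.

# Split a feature table into gene ids and a numeric matrix.
feature_matrix <- function(x) {
  if (is.matrix(x)) {
    genes <- rownames(x) %||% as.character(seq_len(nrow(x)))
    return(list(genes = genes, X = x))
  }
  stopifnot(is.data.frame(x))
  if ("gene" %in% names(x)) {
    genes <- as.character(x$gene)
    X <- as.matrix(x[setdiff(names(x), "gene")])
  } else {
    genes <- as.character(seq_len(nrow(x)))
    X <- as.matrix(x)
  }
  storage.mode(X) <- "double"
  rownames(X) <- genes
  list(genes = genes, X = X)
}

#' Clean a raw feature table
#'
#' Applies the missing-value policy: rows (genes) whose fraction of missing
#' features is at least `sample_missing_max` are removed first; remaining
#' columns with a missing fraction below `feature_missing_max` are
#' mean-imputed. With the default 0.5% thresholds and 14 features, any row
#' with even one missing value (7.1%) is removed, so imputation only
#' becomes active on much wider tables — the thresholds are exposed so the
#' policy can be relaxed.
#'
#' @param x Feature table: tibble with a `gene` column plus numeric
#'   columns, or a numeric matrix.
#' @param feature_missing_max Columns missing less than this fraction are
#'   mean-imputed. Default 0.005.
#' @param sample_missing_max Rows missing at least this fraction are
#'   dropped. Default 0.005.
#' @return A tibble (`gene` + features) with no missing values.
#' @export
clean_features <- function(x, feature_missing_max = 0.005, sample_missing_max = 0.005) {
  stopifnot(
    feature_missing_max >= 0, feature_missing_max <= 1,
    sample_missing_max >= 0, sample_missing_max <= 1
  )
  fm <- feature_matrix(x)
  X <- fm$X
  row_frac <- rowMeans(is.na(X))
  keep <- row_frac < sample_missing_max
  if (!any(keep)) {
    abort("All rows were removed by the missing-value filter.",
      class = "netprio_empty_input"
    )
  }
  X <- X[keep, , drop = FALSE]
  col_frac <- colMeans(is.na(X))
  for (j in which(col_frac > 0)) {
    if (col_frac[j] < feature_missing_max) {
      X[is.na(X[, j]), j] <- mean(X[, j], na.rm = TRUE)
    } else {
      abort(sprintf(
        "Column '%s' is missing %.1f%% of values after row filtering (>= feature_missing_max); cannot impute.",
        colnames(X)[j], 100 * col_frac[j]
      ))
    }
  }
  tibble::as_tibble(cbind(
    tibble::tibble(gene = fm$genes[keep]),
    tibble::as_tibble(X)
  ))
}

#' Z-score standardization
#'
#' Centers and scales every feature column to mean 0, SD 1 (population SD,
#' i.e. divisor `n`). Constant columns map to all zeros. Idempotent up to
#' numerical precision.
#'
#' @inheritParams clean_features
#' @return A tibble of the same shape with standardized values.
#' @export
standardize_features <- function(x) {
  fm <- feature_matrix(x)
  X <- fm$X
  if (anyNA(X)) abort("Standardization requires a fully observed matrix; run clean_features() first.")
  mu <- colMeans(X)
  sd_pop <- sqrt(colMeans(sweep(X, 2, mu)^2))
  Z <- sweep(X, 2, mu)
  nz <- sd_pop > 0
  Z[, nz] <- sweep(Z[, nz, drop = FALSE], 2, sd_pop[nz], "/")
  Z[, !nz] <- 0
  tibble::as_tibble(cbind(tibble::tibble(gene = fm$genes), tibble::as_tibble(Z)))
}

# squared Euclidean distances from rows of X to rows of C
dist2 <- function(X, C) {
  outer(rowSums(X^2), rep(1, nrow(C))) +
    outer(rep(1, nrow(X)), rowSums(C^2)) -
    2 * X %*% t(C)
}

# greedy k-means++ seeding (several candidates per step, keep the one that
# minimizes the potential), as in the reference scikit-learn implementation
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  first <- sample.int(n, 1)
  centers[1, ] <- X[first, ]
  if (k == 1) return(centers)
  d2 <- pmax(dist2(X, centers[1, , drop = FALSE])[, 1], 0)
  n_cand <- 2L + as.integer(floor(log(k)))
  for (j in 2:k) {
    pot <- sum(d2)
    if (pot <= 0) {
      cand <- sample.int(n, n_cand, replace = TRUE)
    } else {
      cand <- sample.int(n, n_cand, replace = TRUE, prob = d2 / pot)
    }
    best_pot <- Inf
    best <- cand[1]
    best_d2 <- d2
    for (c_i in cand) {
      nd2 <- pmin(d2, pmax(dist2(X, X[c_i, , drop = FALSE])[, 1], 0))
      if (sum(nd2) < best_pot) {
        best_pot <- sum(nd2)
        best <- c_i
        best_d2 <- nd2
      }
    }
    centers[j, ] <- X[best, ]
    d2 <- best_d2
  }
  centers
}

#' Seeded K-means clustering (Lloyd's algorithm)
#'
#' K-means with greedy k-means++ initialization and Lloyd iterations,
#' deterministic given `seed`. Iteration stops when the summed squared
#' centroid shift drops below `tol` or after `max_iter` sweeps. Empty
#' clusters are re-seeded with the point farthest from its centroid.
#'
#' @param x Feature table or numeric matrix (see [clean_features()]).
#' @param k Number of clusters, `1 <= k <= n`.
#' @param seed RNG seed.
#' @param max_iter Maximum Lloyd iterations. Default 300.
#' @param tol Convergence tolerance on the squared centroid shift.
#'   Default 1e-4.
#' @param n_init Number of seeded initializations; the run with the lowest
#'   WCSS wins. Default 1 (fully reproducible single init).
#' @return A list: `labels` (integer 1..k per row), `centroids`, `wcss`,
#'   `iterations`.
#' @export
kmeans_fit <- function(x, k, seed = 42, max_iter = 300, tol = 1e-4, n_init = 1) {
  fm <- feature_matrix(x)
  X <- fm$X
  n <- nrow(X)
  if (k < 1 || k > n) {
    abort(sprintf("`k` must be in [1, %d].", n), class = "netprio_parameter_error")
  }
  runs <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_init), function(i) lloyd_once(X, k, max_iter, tol))
  })
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "wcss"))]]
  best$genes <- fm$genes
  best
}

lloyd_once <- function(X, k, max_iter, tol) {
  n <- nrow(X)
  C <- kmeanspp_init(X, k)
  labels <- integer(n)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    D2 <- dist2(X, C)
    labels <- max.col(-D2, ties.method = "first")
    newC <- C
    for (j in seq_len(k)) {
      idx <- which(labels == j)
      if (length(idx) == 0L) {
        # re-seed an empty cluster with the worst-fit point
        far <- which.max(D2[cbind(seq_len(n), labels)])
        newC[j, ] <- X[far, ]
        labels[far] <- j
      } else {
        newC[j, ] <- colMeans(X[idx, , drop = FALSE])
      }
    }
    shift <- sum((newC - C)^2)
    C <- newC
    if (shift < tol || iter >= max_iter) break
  }
  D2 <- dist2(X, C)
  labels <- max.col(-D2, ties.method = "first")
  wcss <- sum(pmax(D2[cbind(seq_len(n), labels)], 0))
  list(labels = labels, centroids = C, wcss = wcss, iterations = iter)
}

#' Choose the number of clusters by the elbow criterion
#'
#' Fits K-means for every `k` in `k_range`, computes the within-cluster sum
#' of squares (WCSS) curve, and picks the interior `k` maximizing the
#' second difference `WCSS(k-1) - 2 WCSS(k) + WCSS(k+1)` (ties go to the
#' smallest `k`). When the strongest second difference is below 5% of
#' `WCSS(1)` the elbow is flagged as weak: the data show no marked
#' curvature and the chosen `k` should be treated with caution.
#'
#' @inheritParams kmeans_fit
#' @param k_range Candidate cluster numbers (contiguous ascending range,
#'   default 1:10; capped at `n`).
#' @return An `elbow_result`: `chosen_k`, `labels`, `centroids`, `wcss`
#'   (tibble `k`, `wcss`), `weak_elbow`, plus the full per-k fits.
#' @export
elbow_select_k <- function(x, k_range = 1:10, seed = 42, max_iter = 300, tol = 1e-4) {
  fm <- feature_matrix(x)
  n <- nrow(fm$X)
  k_range <- k_range[k_range <= n]
  if (length(k_range) < 3) {
    abort("`k_range` must contain at least 3 usable values for elbow selection.",
      class = "netprio_parameter_error"
    )
  }
  fits <- lapply(k_range, function(k) {
    kmeans_fit(fm$X, k, seed = stage_seed(seed, paste0("kmeans", k)),
      max_iter = max_iter, tol = tol)
  })
  wcss <- vapply(fits, `[[`, numeric(1), "wcss")
  interior <- 2:(length(k_range) - 1)
  second_diff <- wcss[interior - 1] - 2 * wcss[interior] + wcss[interior + 1]
  best_i <- interior[which.max(second_diff)]
  chosen_k <- k_range[best_i]
  weak <- max(second_diff) < 0.05 * wcss[1]
  if (weak) {
    warn(sprintf(
      "Weak elbow: strongest WCSS curvature is below 5%% of WCSS(1); chosen k = %d is not well supported.",
      chosen_k
    ))
  }
  structure(
    list(
      chosen_k = chosen_k,
      labels = fits[[best_i]]$labels,
      centroids = fits[[best_i]]$centroids,
      wcss = tibble::tibble(k = k_range, wcss = wcss),
      weak_elbow = weak,
      genes = fm$genes,
      fits = fits
    ),
    class = "elbow_result"
  )
}

#' @export
print.elbow_result <- function(x, ...) {
  cat(sprintf(
    "<elbow_result> chosen k = %d over k in [%d, %d]%s\n",
    x$chosen_k, min(x$wcss$k), max(x$wcss$k),
    if (x$weak_elbow) " (weak elbow)" else ""
  ))
  invisible(x)
}

# average path length of an unsuccessful BST search; the isolation-depth
# normalizer c(m) = 2 H(m-1) - 2 (m-1)/m
avg_path_length <- function(m) {
  ifelse(m > 1, 2 * (digamma(m) + 0.5772156649015329) - 2 * (m - 1) / m, 0)
}

# Grow one isolation tree on rows `idx` of X; returns a nested list.
grow_itree <- function(X, idx, depth, height_limit) {
  m <- length(idx)
  if (m <= 1 || depth >= height_limit) {
    return(list(leaf = TRUE, size = m))
  }
  sub <- X[idx, , drop = FALSE]
  lo <- apply(sub, 2, min)
  hi <- apply(sub, 2, max)
  usable <- which(hi > lo)
  if (length(usable) == 0) {
    return(list(leaf = TRUE, size = m))
  }
  f <- usable[sample.int(length(usable), 1)]
  split <- runif(1, lo[f], hi[f])
  left <- idx[X[idx, f] < split]
  right <- idx[X[idx, f] >= split]
  list(
    leaf = FALSE, feature = f, split = split,
    left = grow_itree(X, left, depth + 1L, height_limit),
    right = grow_itree(X, right, depth + 1L, height_limit)
  )
}

# Path lengths of all rows of X through one tree (vectorized descent).
itree_paths <- function(tree, X, idx, depth, out) {
  if (tree$leaf) {
    out[idx] <- depth + avg_path_length(tree$size)
    return(out)
  }
  go_left <- X[idx, tree$feature] < tree$split
  if (any(go_left)) out <- itree_paths(tree$left, X, idx[go_left], depth + 1, out)
  if (any(!go_left)) out <- itree_paths(tree$right, X, idx[!go_left], depth + 1, out)
  out
}

#' Isolation Forest anomaly detection
#'
#' Builds an ensemble of isolation trees on seeded subsamples (random
#' feature, uniform random split within the feature's observed range,
#' height limit `ceiling(log2(subsample size))`) and scores every row by
#' `s(x) = 2^(-E[h(x)] / c(m))`, where `E[h(x)]` is the mean path length
#' across trees and `c(m)` the expected unsuccessful-search depth at the
#' subsample size. Scores lie in (0, 1]; short isolation paths (easy to
#' separate) give scores near 1. The `ceiling(contamination * n)` rows with
#' the highest scores are flagged as outliers; rows tied with the cutoff
#' score are all flagged, so the flag set is order-independent.
#'
#' @inheritParams kmeans_fit
#' @param n_trees Number of isolation trees. Default 100.
#' @param subsample_fraction Fraction of rows used to grow each tree.
#'   Default 0.8.
#' @param contamination Expected outlier fraction in (0, 0.5]; sets the
#'   number of flagged rows. Default 0.10.
#' @return An `iforest_result` tibble: `gene`, `anomaly_score`,
#'   `is_outlier`.
#' @export
isolation_forest <- function(x, n_trees = 100, subsample_fraction = 0.8,
                             contamination = 0.10, seed = 42) {
  fm <- feature_matrix(x)
  X <- fm$X
  n <- nrow(X)
  if (n < 2) abort("Isolation forest needs at least 2 rows.", class = "netprio_parameter_error")
  if (!is.numeric(contamination) || contamination <= 0 || contamination > 0.5) {
    abort("`contamination` must lie in (0, 0.5].", class = "netprio_parameter_error")
  }
  m <- max(2L, min(n, as.integer(ceiling(subsample_fraction * n))))
  height_limit <- ceiling(log2(m))
  paths <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_trees), function(t) {
      idx <- sample.int(n, m, replace = FALSE)
      tree <- grow_itree(X, idx, 0L, height_limit)
      itree_paths(tree, X, seq_len(n), 0, numeric(n))
    }, numeric(n))
  })
  mean_path <- rowMeans(paths)
  score <- 2^(-mean_path / avg_path_length(m))
  q <- ceiling(contamination * n)
  cutoff <- sort(score, decreasing = TRUE)[q]
  flagged <- score >= cutoff
  structure(
    tibble::tibble(
      gene = fm$genes,
      anomaly_score = score,
      is_outlier = flagged
    ),
    class = c("iforest_result", "tbl_df", "tbl", "data.frame"),
    subsample_size = m,
    n_flagged_target = q
  )
}

#' Two-component PCA projection
#'
#' Column-centered principal component analysis retaining the first two
#' components. The sign of each component is fixed so its largest-magnitude
#' loading is positive, making projections reproducible across platforms.
#'
#' @inheritParams kmeans_fit
#' @param n_components Number of components to retain. Default 2.
#' @return A list: `scores` (tibble `gene`, `pc1`, `pc2`, ...), `loadings`,
#'   `var_explained` (fraction per retained component, non-increasing).
#' @export
pca_project <- function(x, n_components = 2) {
  fm <- feature_matrix(x)
  X <- fm$X
  n_components <- min(n_components, ncol(X), nrow(X) - 1)
  fit <- prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(fit$rotation))
  load <- fit$rotation[, seq_len(k), drop = FALSE]
  scores <- fit$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(load[, j]))
    if (load[i_max, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  var_all <- fit$sdev^2
  colnames(scores) <- paste0("pc", seq_len(k))
  list(
    scores = tibble::as_tibble(cbind(
      tibble::tibble(gene = fm$genes),
      tibble::as_tibble(scores)
    )),
    loadings = load,
    var_explained = var_all[seq_len(k)] / sum(var_all)
  )
}

#' Direction-aware composite importance score
#'
#' Ranks every gene within each index — descending for indices where large
#' values indicate importance, ascending for path/modularity indices where
#' small values do — using fractional (mean-of-tied-positions) ranks, and
#' averages the ranks into a composite score. Lower composite scores mean
#' higher overall network importance. The two direction sets must exactly
#' partition the feature columns.
#'
#' @param x Feature table (e.g. from [centrality_table()]): `gene` column
#'   plus numeric index columns.
#' @param descending_indices Indices ranked in descending value order.
#' @param ascending_indices Indices ranked in ascending value order.
#' @return A tibble: `gene`, one `rank_<index>` column per index,
#'   `composite_score`, `composite_rank` (fractional ranks of the composite,
#'   ascending), sorted by `composite_rank`.
#' @examples
#' tbl <- tibble::tibble(gene = c("A", "B", "C"), i1 = c(9, 5, 1), i2 = c(9, 1, 5))
#' composite_score(tbl, descending_indices = c("i1", "i2"), ascending_indices = character())
#' @export
composite_score <- function(x,
                            descending_indices = default_descending_indices(),
                            ascending_indices = default_ascending_indices()) {
  fm <- feature_matrix(x)
  cols <- colnames(fm$X)
  if (length(intersect(descending_indices, ascending_indices)) > 0 ||
    !setequal(c(descending_indices, ascending_indices), cols)) {
    abort(
      "`descending_indices` and `ascending_indices` must partition the feature columns exactly.",
      class = "netprio_config_error"
    )
  }
  ranks <- vapply(cols, function(cn) {
    frank(fm$X[, cn], descending = cn %in% descending_indices)
  }, numeric(nrow(fm$X)))
  if (is.null(dim(ranks))) ranks <- matrix(ranks, nrow = 1, dimnames = list(NULL, cols))
  comp <- rowMeans(ranks)
  out <- tibble::as_tibble(cbind(
    tibble::tibble(gene = fm$genes),
    stats::setNames(tibble::as_tibble(ranks), paste0("rank_", cols)),
    tibble::tibble(
      composite_score = comp,
      composite_rank = frank(comp)
    )
  ))
  dplyr::arrange(out, .data$composite_rank, .data$gene)
}

#' Run the full prioritization workflow on a feature table
#'
#' Chains the machine-learning stages on a per-gene feature table (usually
#' the output of [centrality_table()], possibly restricted to a hub set):
#' cleaning, z-score standardization, K-means with elbow selection,
#' Isolation Forest, 2-component PCA, direction-aware composite scoring and
#' the core-gene rule (Isolation-Forest outlier AND composite rank at or
#' under `rank_threshold`). All stochastic stages draw their own substream
#' from `seed`.
#'
#' @inheritParams composite_score
#' @inheritParams isolation_forest
#' @inheritParams elbow_select_k
#' @inheritParams clean_features
#' @param rank_threshold Core-gene composite-rank cutoff. Default 20.
#' @return A `target_prioritization` object; see [tidy.target_prioritization()]
#'   for the per-gene table and [select_core_genes()] for the core set.
#' @export
prioritize_targets <- function(x,
                               descending_indices = default_descending_indices(),
                               ascending_indices = default_ascending_indices(),
                               k_range = 1:10,
                               n_trees = 100,
                               subsample_fraction = 0.8,
                               contamination = 0.10,
                               rank_threshold = 20,
                               feature_missing_max = 0.005,
                               sample_missing_max = 0.005,
                               max_iter = 300,
                               tol = 1e-4,
                               seed = 42) {
  cleaned <- clean_features(x, feature_missing_max, sample_missing_max)
  z <- standardize_features(cleaned)
  elbow <- elbow_select_k(z,
    k_range = k_range, seed = stage_seed(seed, "elbow"),
    max_iter = max_iter, tol = tol
  )
  forest <- isolation_forest(z,
    n_trees = n_trees, subsample_fraction = subsample_fraction,
    contamination = contamination, seed = stage_seed(seed, "iforest")
  )
  pca <- pca_project(z, n_components = 2)
  scored <- composite_score(cleaned,
    descending_indices = descending_indices,
    ascending_indices = ascending_indices
  )
  table <- scored |>
    dplyr::left_join(
      tibble::tibble(gene = elbow$genes, cluster = elbow$labels),
      by = "gene"
    ) |>
    dplyr::left_join(forest, by = "gene") |>
    dplyr::left_join(pca$scores, by = "gene") |>
    dplyr::mutate(is_core = .data$is_outlier & .data$composite_rank <= rank_threshold)
  structure(
    list(
      table = table,
      elbow = elbow,
      pca = pca,
      params = list(
        k_range = k_range, n_trees = n_trees,
        subsample_fraction = subsample_fraction,
        contamination = contamination, rank_threshold = rank_threshold,
        max_iter = max_iter, tol = tol, seed = seed,
        descending_indices = descending_indices,
        ascending_indices = ascending_indices
      )
    ),
    class = "target_prioritization"
  )
}

#' @export
print.target_prioritization <- function(x, ...) {
  cat(sprintf(
    "<target_prioritization> %d genes | k = %d clusters | %d outliers | %d core genes\n",
    nrow(x$table), x$elbow$chosen_k, sum(x$table$is_outlier), sum(x$table$is_core)
  ))
  top <- dplyr::select(
    head(x$table, 5),
    "gene", "composite_score", "composite_rank", "is_outlier", "is_core"
  )
  print(top)
  invisible(x)
}

#' Tidy / summarize a prioritization
#'
#' `tidy()` returns the per-gene table (ranks per index, composite score
#' and rank, cluster label, anomaly score, outlier and core flags, PCA
#' coordinates). `glance()` returns a one-row model summary.
#'
#' @param x A `target_prioritization`.
#' @param ... Unused.
#' @method tidy target_prioritization
#' @export
tidy.target_prioritization <- function(x, ...) x$table

#' @rdname tidy.target_prioritization
#' @method glance target_prioritization
#' @export
glance.target_prioritization <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$table),
    chosen_k = x$elbow$chosen_k,
    weak_elbow = x$elbow$weak_elbow,
    n_outliers = sum(x$table$is_outlier),
    n_core = sum(x$table$is_core),
    pc1_var = x$pca$var_explained[1],
    pc2_var = if (length(x$pca$var_explained) > 1) x$pca$var_explained[2] else NA_real_
  )
}

#' Core-gene selection rule
#'
#' A gene is a core gene when it is simultaneously an Isolation-Forest
#' outlier and within the top composite ranks
#' (`composite_rank <= rank_threshold`).
#'
#' @param pr A `target_prioritization` (or its [tidy()] table).
#' @param rank_threshold Composite-rank cutoff. Default 20.
#' @return A [gene_list] of core genes ordered by composite rank.
#' @export
select_core_genes <- function(pr, rank_threshold = 20) {
  tbl <- if (inherits(pr, "target_prioritization")) pr$table else pr
  stopifnot(all(c("gene", "composite_rank", "is_outlier") %in% names(tbl)))
  sel <- tbl[tbl$is_outlier & tbl$composite_rank <= rank_threshold, , drop = FALSE]
  sel <- sel[order(sel$composite_rank, sel$gene, method = "radix"), , drop = FALSE]
  gene_list(sel$gene, name = "core_genes")
}
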