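test_that("clean_features applies the row-first missing-value policy", {
  full <- tibble::tibble(gene = c("A", "B"), x = c(1, 2), y = c(3, 4))
  expect_equal(clean_features(full), full)

  # one gene missing 3 of 14 values (21.4% >= 0.5%) is dropped
  m <- matrix(rnorm(22 * 14), 22, 14,
    dimnames = list(sprintf("G%02d", 1:22), centrality_columns())
  )
  m[3, 1:3] <- NA
  cleaned <- clean_features(m)
  expect_equal(nrow(cleaned), 21)
  expect_false("G03" %in% cleaned$gene)
  expect_false(anyNA(cleaned))

  # wide-threshold case: sub-threshold column gets mean-imputed
  m2 <- matrix(seq_len(1000 * 14), 1000, 14,
    dimnames = list(sprintf("G%04d", 1:1000), centrality_columns())
  )
  m2[1:4, 2] <- NA
  cleaned2 <- clean_features(m2, feature_missing_max = 0.005, sample_missing_max = 0.5)
  expect_equal(nrow(cleaned2), 1000)
  expect_equal(
    cleaned2[[centrality_columns()[2]]][1],
    mean(m2[5:1000, 2])
  )

  allna <- matrix(NA_real_, 3, 2, dimnames = list(c("A", "B", "C"), c("x", "y")))
  expect_error(clean_features(allna), class = "netprio_empty_input")
})

test_that("standardization uses population SD, zeroes constant columns, is idempotent", {
  tbl <- tibble::tibble(gene = c("A", "B", "C"), v = c(1, 2, 3), const = c(7, 7, 7))
  z <- standardize_features(tbl)
  expect_equal(z$v, c(-1.224744871391589, 0, 1.224744871391589), tolerance = 1e-12)
  expect_equal(z$const, c(0, 0, 0))
  z2 <- standardize_features(z)
  expect_equal(as.matrix(z2[-1]), as.matrix(z[-1]), tolerance = 1e-9)
  # every non-constant column: mean 0, population SD 1
  expect_equal(mean(z$v), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(z$v^2)), 1, tolerance = 1e-9)
})

test_that("kmeans recovers exact structure in easy cases and rejects bad k", {
  X <- matrix(c(0, 0, 0.1, 0, 10, 10, 10.1, 10), 4, 2, byrow = TRUE)
  fit <- kmeans_fit(X, 2, seed = 1)
  expect_equal(fit$labels[1], fit$labels[2])
  expect_equal(fit$labels[3], fit$labels[4])
  expect_false(fit$labels[1] == fit$labels[3])

  fit1 <- kmeans_fit(X, 1, seed = 1)
  expect_equal(fit1$centroids[1, ], colMeans(X))
  expect_equal(fit1$wcss, sum(sweep(X, 2, colMeans(X))^2), tolerance = 1e-12)

  expect_error(kmeans_fit(X, 5, seed = 1), class = "netprio_parameter_error")

  # cross-check WCSS against stats::kmeans at the same k on benign data
  set.seed(9)
  Y <- rbind(
    matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 8), 20, 2)
  )
  ours <- kmeans_fit(Y, 2, seed = 4)
  ref <- stats::kmeans(Y, 2, nstart = 10)
  expect_equal(ours$wcss, ref$tot.withinss, tolerance = 1e-6)
})

test_that("WCSS is non-increasing in k", {
  set.seed(11)
  X <- matrix(rnorm(60 * 3), 60, 3)
  w <- vapply(1:8, function(k) kmeans_fit(X, k, seed = 5)$wcss, numeric(1))
  expect_true(all(diff(w) <= 1e-8))
})

test_that("elbow selection finds planted cluster counts and flags weak elbows", {
  fc <- generate_feature_clouds(n_per_cluster = 30, n_clusters = 3, separation = 10, n_outliers = 0, seed = 2)
  el <- elbow_select_k(fc$features, seed = 2)
  expect_equal(el$chosen_k, 3)
  expect_false(el$weak_elbow)
  expect_true(all(diff(el$wcss$wcss) <= 1e-8))
  expect_true(all(el$labels >= 1 & el$labels <= el$chosen_k))

  # a single high-dimensional spherical cloud has no real curvature:
  # an argmax is still returned, with the weak-elbow warning
  set.seed(3)
  blob <- matrix(rnorm(80 * 8), 80, 8)
  expect_warning(el2 <- elbow_select_k(blob, seed = 3), "Weak elbow")
  expect_true(el2$weak_elbow)
  expect_true(el2$chosen_k %in% 2:9)

  expect_error(elbow_select_k(blob, k_range = 1:2), class = "netprio_parameter_error")
})

test_that("isolation forest isolates a planted extreme point and flags by count", {
  set.seed(5)
  X <- rbind(matrix(rnorm(200), 100, 2), c(10, 10))
  fo <- isolation_forest(X, seed = 5)
  expect_true(fo$is_outlier[101])
  expect_equal(which.max(fo$anomaly_score), 101L)
  expect_true(all(fo$anomaly_score > 0 & fo$anomaly_score <= 1))

  # contamination 0.10 on n = 22 flags ceiling(2.2) = 3 genes
  set.seed(6)
  Y <- matrix(rnorm(22 * 14), 22, 14)
  fo22 <- isolation_forest(Y, seed = 6)
  expect_equal(sum(fo22$is_outlier), 3L)
  # flagged genes carry the highest scores
  expect_true(min(fo22$anomaly_score[fo22$is_outlier]) >=
    max(fo22$anomaly_score[!fo22$is_outlier]))

  # identical rows: all scores equal, the tie rule flags everyone
  Z <- matrix(1, 10, 3)
  foz <- isolation_forest(Z, seed = 1)
  expect_equal(length(unique(foz$anomaly_score)), 1L)
  expect_true(all(foz$is_outlier))

  expect_error(isolation_forest(Y, contamination = 0), class = "netprio_parameter_error")
  expect_error(isolation_forest(Y, contamination = 0.6), class = "netprio_parameter_error")
})

test_that("PCA projection has fixed signs, ordered variance, preserves rank-2 geometry", {
  # perfectly collinear data: PC1 explains everything
  t <- seq(-2, 2, length.out = 20)
  X <- cbind(t, 2 * t)
  p <- pca_project(X)
  expect_equal(p$var_explained[1], 1, tolerance = 1e-12)

  # rank-2 data: projection to 2 components preserves pairwise distances
  set.seed(8)
  B <- matrix(rnorm(6), 3, 2)
  Y <- matrix(rnorm(30 * 3), 30, 3)[, 1:2] %*% t(B)[1:2, , drop = FALSE]
  p2 <- pca_project(Y)
  d_orig <- dist(sweep(Y, 2, colMeans(Y)))
  d_proj <- dist(as.matrix(p2$scores[, c("pc1", "pc2")]))
  expect_equal(as.vector(d_proj), as.vector(d_orig), tolerance = 1e-9)

  # variance fractions non-increasing, sum <= 1; largest loading positive
  set.seed(9)
  W <- matrix(rnorm(40 * 5), 40, 5)
  p3 <- pca_project(W)
  expect_true(all(diff(p3$var_explained) <= 1e-12))
  expect_true(sum(p3$var_explained) <= 1 + 1e-12)
  for (j in 1:2) {
    expect_true(p3$loadings[which.max(abs(p3$loadings[, j])), j] > 0)
  }
})

test_that("composite score matches the hand-ranked example and direction rules", {
  tbl <- tibble::tibble(
    gene = c("A", "B", "C"),
    i1 = c(9, 5, 1),
    i2 = c(9, 1, 5)
  )
  res <- composite_score(tbl, descending_indices = c("i1", "i2"), ascending_indices = character())
  expect_equal(res$composite_score[res$gene == "A"], 1.0)
  expect_equal(res$composite_score[res$gene == "B"], 2.5)
  expect_equal(res$composite_score[res$gene == "C"], 2.5)

  # a gene ranked 1 everywhere scores exactly 1
  expect_equal(min(res$composite_rank), 1)

  # invalid direction partitions are rejected
  expect_error(
    composite_score(tbl, descending_indices = c("i1", "i2"), ascending_indices = "i1"),
    class = "netprio_config_error"
  )
  expect_error(
    composite_score(tbl, descending_indices = "i1", ascending_indices = character()),
    class = "netprio_config_error"
  )
})

test_that("composite score conserves rank sums and ignores monotone transforms", {
  set.seed(12)
  for (rep in 1:5) {
    n <- sample(5:40, 1)
    tbl <- tibble::as_tibble(
      matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("m", 1:4)))
    )
    tbl <- dplyr::bind_cols(tibble::tibble(gene = sprintf("g%02d", 1:n)), tbl)
    res <- composite_score(tbl,
      descending_indices = c("m1", "m2", "m3"),
      ascending_indices = "m4"
    )
    expect_equal(mean(res$composite_score), (n + 1) / 2, tolerance = 1e-12)
    # strictly monotone transform of one index leaves everything unchanged
    tbl2 <- dplyr::mutate(tbl, m2 = exp(3 * m2) + 1)
    res2 <- composite_score(tbl2,
      descending_indices = c("m1", "m2", "m3"),
      ascending_indices = "m4"
    )
    expect_equal(res$composite_score, res2$composite_score)
    # column order is irrelevant
    res3 <- composite_score(tbl[, c("gene", "m4", "m2", "m1", "m3")],
      descending_indices = c("m1", "m2", "m3"),
      ascending_indices = "m4"
    )
    expect_equal(
      res3$composite_score[match(res$gene, res3$gene)],
      res$composite_score
    )
  }
})

test_that("core-gene rule requires both the outlier flag and the rank cutoff", {
  tbl <- tibble::tibble(
    gene = c("A", "B", "C", "D"),
    composite_rank = c(5, 1, 21, 2),
    is_outlier = c(TRUE, FALSE, TRUE, TRUE)
  )
  core <- select_core_genes(tbl, rank_threshold = 20)
  expect_equal(gene_symbols(core), c("D", "A")) # ordered by rank; B and C excluded
})

test_that("the full prioritization is deterministic given a seed", {
  sim <- generate_ppi(n_nodes = 80, n_hubs = 2, hub_extra_degree = 20, seed = 21)
  ct <- centrality_table(sim$graph, epc_iterations = 200, seed = 3)
  p1 <- suppressWarnings(prioritize_targets(ct, k_range = 1:6, seed = 42))
  p2 <- suppressWarnings(prioritize_targets(ct, k_range = 1:6, seed = 42))
  expect_identical(tidy(p1), tidy(p2))
  expect_identical(glance(p1), glance(p2))

  # and the tidy table carries the documented columns
  expect_true(all(c(
    "gene", "composite_score", "composite_rank", "cluster",
    "anomaly_score", "is_outlier", "is_core", "pc1", "pc2"
  ) %in% names(tidy(p1))))
  expect_true(all(paste0("rank_", centrality_columns()) %in% names(tidy(p1))))
})
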