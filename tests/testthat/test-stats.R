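# The enumeration oracle draws every possible K-subset of a universe of N
# items (M of them marked) and counts how many subsets share >= x marked
# items — exact rational arithmetic at small N.
enumerate_tail <- function(N, K, M, x) {
  marked <- seq_len(M)
  hits <- 0
  total <- 0
  sets <- combn(N, K)
  for (i in seq_len(ncol(sets))) {
    total <- total + 1
    if (sum(sets[, i] %in% marked) >= x) hits <- hits + 1
  }
  hits / total
}

test_that("hypergeometric tail matches exhaustive draw enumeration at small N", {
  cases <- list(
    c(10, 5, 4, 4), c(10, 5, 4, 0), c(10, 5, 4, 2),
    c(8, 3, 5, 1), c(8, 3, 5, 3), c(12, 6, 6, 4),
    c(6, 2, 2, 2), c(9, 4, 7, 4)
  )
  for (cs in cases) {
    expect_equal(
      hypergeom_tail(cs[1], cs[2], cs[3], cs[4], log = FALSE),
      enumerate_tail(cs[1], cs[2], cs[3], cs[4]),
      tolerance = 1e-12
    )
  }
  # the worked example: N=10, K=5, M=4, x=4 -> 1/42
  expect_equal(hypergeom_tail(10, 5, 4, 4, log = FALSE), 1 / 42, tolerance = 1e-14)
})

test_that("probability masses sum to one for random parameters up to 500", {
  set.seed(14)
  for (rep in 1:20) {
    N <- sample(2:500, 1)
    K <- sample(0:N, 1)
    M <- sample(0:N, 1)
    total <- sum(vapply(0:min(K, M), function(j) {
      hypergeom_tail(N, K, M, j, log = FALSE) -
        hypergeom_tail(N, K, M, j + 1, log = FALSE)
    }, numeric(1)))
    expect_equal(total, 1, tolerance = 1e-12)
  }
})

test_that("tail is non-increasing in x, symmetric in K and M, and edge-safe", {
  set.seed(15)
  for (rep in 1:10) {
    N <- sample(5:200, 1)
    K <- sample(1:N, 1)
    M <- sample(1:N, 1)
    tails <- vapply(0:min(K, M), function(j) hypergeom_tail(N, K, M, j, log = FALSE), numeric(1))
    expect_true(all(diff(tails) <= 1e-12))
    x <- sample(0:min(K, M), 1)
    expect_equal(
      hypergeom_tail(N, K, M, x),
      hypergeom_tail(N, M, K, x),
      tolerance = 1e-12
    )
  }
  expect_equal(hypergeom_tail(10, 5, 4, 0, log = FALSE), 1)
  expect_identical(hypergeom_tail(10, 5, 4, 5), -Inf) # impossible overlap
})

test_that("log-space tail agrees with phyper across magnitudes", {
  cases <- list(
    c(19871, 742, 5583, 364), c(19871, 742, 5583, 100),
    c(500, 100, 100, 50), c(100, 10, 10, 10)
  )
  for (cs in cases) {
    expect_equal(
      hypergeom_tail(cs[1], cs[2], cs[3], cs[4]),
      stats::phyper(cs[4] - 1, cs[3], cs[1] - cs[3], cs[2],
        lower.tail = FALSE, log.p = TRUE
      ),
      tolerance = 1e-9
    )
  }
})

test_that("overlap_test computes the intersection after normalization", {
  # identical 3-gene lists in a universe of 10: p = 1/C(10,3) = 1/120
  r <- overlap_test(c("a", "b", "c"), c("A", "B", "C"), universe_N = 10)
  expect_equal(r$observed_x, 3)
  expect_equal(r$p_value, 1 / 120, tolerance = 1e-12)
  expect_equal(r$expected, 9 / 10)

  # disjoint lists: x = 0, p = 1
  r0 <- overlap_test(c("A", "B"), c("C", "D"), universe_N = 50)
  expect_equal(r0$observed_x, 0)
  expect_equal(r0$p_value, 1)

  expect_error(overlap_test(c("A", "B"), c("C", "D"), universe_N = 3), "universe_N")

  td <- tidy(r)
  expect_equal(td$log10_p, log10(1 / 120), tolerance = 1e-9)
})

test_that("BH adjustment reproduces the step-up closed forms", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.05, 0.05, 0.05)), c(0.05, 0.05, 0.05))
  expect_equal(bh_adjust(c(0.005, 0.04, 0.8)), c(0.015, 0.06, 0.8))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
})

test_that("ora_enrich ranks planted structure correctly", {
  universe <- sprintf("G%03d", 1:100)
  query <- universe[1:10]
  collection <- list(
    SAME = query,
    DISJOINT = universe[50:60],
    PARTIAL = universe[6:15]
  )
  res <- ora_enrich(query, collection, universe)
  expect_equal(res$set_name[1], "SAME")
  # identical set achieves the minimal possible p for its size
  expect_equal(
    res$p_value[res$set_name == "SAME"],
    hypergeom_tail(100, 10, 10, 10, log = FALSE),
    tolerance = 1e-12
  )
  expect_equal(res$p_value[res$set_name == "DISJOINT"], 1)
  expect_true(all(res$bh_fdr >= res$p_value - 1e-15))
  expect_true(all(diff(res$p_value) >= -1e-15))

  # query genes outside the universe are dropped with a warning
  expect_warning(
    ora_enrich(c(query, "NOT_THERE"), collection, universe),
    "outside the universe"
  )
  expect_warning(res0 <- ora_enrich(query, list(), universe), "Empty")
  expect_equal(nrow(res0), 0)
})

test_that("ora_enrich p-values are super-uniform under the null", {
  universe <- sprintf("G%03d", 1:200)
  collection <- list(S1 = universe[1:20], S2 = universe[21:60], S3 = universe[101:130])
  set.seed(77)
  hits <- 0
  n_rep <- 2000
  for (i in seq_len(n_rep)) {
    query <- sample(universe, 15)
    res <- ora_enrich(query, collection["S1"], universe)
    if (res$p_value[1] <= 0.05) hits <- hits + 1
  }
  expect_lte(hits / n_rep, 0.07)
})

test_that("GMT files round-trip", {
  f <- withr::local_tempfile(fileext = ".gmt")
  sets <- list(ALPHA = c("TP53", "TNF"), BETA = c("EGFR", "INS", "ESR1"))
  write_gmt(sets, f)
  back <- read_gmt(f)
  expect_equal(back$set_name, c("ALPHA", "BETA"))
  expect_equal(back$genes[[2]], c("EGFR", "INS", "ESR1"))

  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines("ONLYNAME", bad)
  expect_error(read_gmt(bad), class = "netprio_format_error")
})
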