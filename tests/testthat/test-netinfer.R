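# MI estimation, DPI pruning, top-N sparsification.

test_that("plug-in MI reproduces closed-form contingency values", {
  expect_equal(mi_from_counts(matrix(c(2, 0, 0, 2), 2)), 1.0, tolerance = 1e-12)
  expect_equal(mi_from_counts(matrix(c(1, 1, 1, 1), 2)), 0.0, tolerance = 1e-12)
  expect_equal(mi_from_counts(matrix(c(3, 1, 1, 3), 2)), 0.1887219,
               tolerance = 1e-6)
})

test_that("MI is symmetric and exactly rank-invariant", {
  set.seed(2)
  x <- stats::rnorm(60)
  y <- x + stats::rnorm(60)
  expect_identical(mutual_information(x, y), mutual_information(y, x))
  # strictly increasing transforms change nothing (equal-frequency binning)
  expect_identical(mutual_information(exp(x), y), mutual_information(x, y))
  expect_identical(mutual_information(x, y^3 + 2 * y), mutual_information(x, y))
  expect_error(mutual_information(x, y[1:10]), "equal length")
  expect_error(mutual_information(x[1:5], y[1:5]), "at least 8")
  expect_warning(mi0 <- mutual_information(rep(1, 60), y), "constant")
  expect_equal(mi0, 0)
})

test_that("sqrt-n binning floors at the announced bin count", {
  set.seed(8)
  x <- stats::rnorm(60); y <- stats::rnorm(60)
  # B = 7 at n = 60; an explicit 7-bin config must agree with the default
  expect_identical(mutual_information(x, y, mi_config(n_bins = 7L)),
                   mutual_information(x, y))
  expect_error(mi_config(n_bins = 1L), "n_bins")
})

test_that("chance-level MI stays at the analytic plug-in bias floor", {
  # independent vectors: E[plug-in MI] ~ (B-1)^2 / (2 n ln 2) bits to first
  # order; with B = floor(sqrt(n)) the table has ~n cells, so higher-order
  # terms are non-negligible and the observed floor sits some 10-20% above
  # the first-order value. Chance MI must agree with the analytic floor in
  # magnitude — any genuine dependence signal sits far above it.
  set.seed(12)
  n <- 1000
  B <- floor(sqrt(n))
  bias <- (B - 1)^2 / (2 * n * log(2))
  plugin <- replicate(20, mutual_information(stats::rnorm(n), stats::rnorm(n)))
  expect_gt(mean(plugin) / bias, 0.5)
  expect_lt(mean(plugin) / bias, 1.5)
  # Miller-Madow shrinks the chance level toward zero
  mm <- replicate(20, mutual_information(stats::rnorm(n), stats::rnorm(n),
                                         mi_config(estimator = "miller_madow")))
  expect_lt(mean(mm), mean(plugin))
})

test_that("MI of a profile with itself dominates all other pairs", {
  set.seed(13)
  m <- mk_matrix(matrix(stats::rnorm(8 * 50), 8))
  x <- m[1, ]
  others <- apply(m[-1, ], 1, function(y) mutual_information(x, y))
  expect_gt(mutual_information(x, x), max(others))
})

test_that("mi_matrix equals pairwise mutual_information calls", {
  set.seed(4)
  m <- mk_matrix(matrix(stats::rnorm(6 * 40), 6, 40))
  m[3, ] <- 7  # constant gene
  e <- suppressWarnings(mi_matrix(m))
  expect_equal(nrow(e), choose(6, 2))
  expect_s3_class(e, "mi_edges")
  for (r in seq_len(nrow(e))) {
    expected <- suppressWarnings(
      mutual_information(m[e$gene_a[r], ], m[e$gene_b[r], ]))
    expect_equal(e$mi[r], expected, tolerance = 1e-12)
  }
  expect_true(all(e$mi[e$gene_a == "g03" | e$gene_b == "g03"] == 0))
  e3 <- mi_matrix(m[1:3, ])
  expect_equal(nrow(e3), 3)
})

test_that("within-module MI beats the upper tail of background MI", {
  ok <- 0L
  for (s in 1:5) {
    co <- generate_cohort(two_module_config(seed = s, latent = 0.8))
    norm <- normalize_counts(co$counts)
    e <- mi_matrix(norm$normalized,
                   co$labels$sample_id[co$labels$phenotype == "tumor"])
    key <- paste(e$gene_a, e$gene_b)
    planted <- key %in% paste(co$truth$pairs$gene_a, co$truth$pairs$gene_b)
    ok <- ok + (stats::median(e$mi[planted]) >
                  stats::quantile(e$mi[!planted], 0.95))
  }
  expect_gte(ok, 4L)
})

test_that("DPI removes the forced triangle edge and keeps bridges", {
  e <- mi_edges(c("A", "B", "A", "C"), c("B", "C", "C", "D"),
                c(0.5, 0.4, 0.1, 0.05))
  pruned <- dpi_prune(e, 0)
  expect_false(any(pruned$gene_a == "A" & pruned$gene_b == "C"))
  # C-D is in no triangle: always kept, however weak
  expect_true(any(pruned$gene_a == "C" & pruned$gene_b == "D"))
  expect_equal(nrow(pruned), 3)
  expect_error(dpi_prune(e, 1), "tolerance")
})

test_that("DPI equals the exhaustive triangle oracle on random graphs", {
  for (s in 1:20) {
    set.seed(s)
    nodes <- sprintf("n%d", 1:8)
    pairs <- utils::combn(nodes, 2)
    pick <- stats::runif(ncol(pairs)) < 0.5
    if (sum(pick) < 3) next
    e <- mi_edges(pairs[1, pick], pairs[2, pick], stats::runif(sum(pick)))
    tol <- sample(c(0, 0, 0.1), 1)
    got <- dpi_prune(e, tol)
    want <- oracle_dpi(e, tol)
    expect_equal(paste(got$gene_a, got$gene_b),
                 paste(want$gene_a, want$gene_b), info = sprintf("seed %d", s))
  }
})

test_that("top-N cut-offs are nested prefixes", {
  e <- random_edges(500, 60, seed = 6)
  expect_equal(nrow(top_n(e, 1)), 1)
  expect_equal(top_n(e, 1)$mi, max(e$mi))
  expect_identical(top_n(e, 1e6), e)
  t100 <- top_n(e, 100)
  t300 <- top_n(e, 300)
  expect_identical(paste(t100$gene_a, t100$gene_b),
                   paste(t300$gene_a, t300$gene_b)[1:100])
  expect_error(top_n(e, 0), "positive")
})
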