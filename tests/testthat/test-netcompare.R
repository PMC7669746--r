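# Multi-network set algebra and cut-off curves.

keyed <- function(...) {
  ks <- c(...)
  df <- data.frame(gene_a = sub("-.*", "", ks), gene_b = sub(".*-", "", ks))
  df
}

test_that("three-network worked example enumerates every region", {
  nets <- list(A = keyed("e1-x", "e2-x", "e3-x"),
               B = keyed("e2-x", "e3-x", "e4-x"),
               C = keyed("e3-x", "e4-x", "e5-x"))
  res <- intersect_networks(nets)
  expect_equal(paste(res$shared_all$gene_a), "e3")
  expect_equal(paste(res$group_specific$A$gene_a), "e1")
  expect_equal(paste(res$group_specific$C$gene_a), "e5")
  expect_equal(nrow(res$group_specific$B), 0)
  expect_equal(unname(res$pairwise_shared["A|B"]), 2)
  expect_equal(unname(res$totals), c(3L, 3L, 3L))
})

test_that("identical networks share everything; nothing is specific", {
  e <- random_edges(50, 30, seed = 1)
  res <- intersect_networks(list(a = e, b = e, c = e), control_name = "a")
  expect_equal(nrow(res$shared_all), 50)
  expect_true(all(vapply(res$group_specific, nrow, integer(1)) == 0))
  expect_equal(nrow(res$cancer_only), 0)
  expect_error(intersect_networks(list(a = e, b = e), control_name = "zz"),
               "unknown control")
})

test_that("random collections match the membership-bitmask oracle", {
  for (s in 1:5) {
    nets <- lapply(1:5, function(i) random_edges(300, 60, seed = s * 10 + i))
    names(nets) <- sprintf("n%d", 1:5)
    res <- intersect_networks(nets, control_name = "n1")
    want <- oracle_regions(lapply(nets, function(e) paste(e$gene_a, e$gene_b)))
    got <- stats::setNames(as.integer(res$regions), names(res$regions))
    expect_identical(got[order(names(got))], want[order(names(want))])
    # region sizes add up to the union
    expect_equal(sum(res$regions),
                 length(unique(unlist(lapply(nets, function(e)
                   paste(e$gene_a, e$gene_b))))))
    # cancer_only against a direct recomputation
    keys <- lapply(nets, function(e) paste(e$gene_a, e$gene_b, sep = "\t"))
    want_co <- setdiff(Reduce(intersect, keys[2:5]), keys$n1)
    expect_setequal(paste(res$cancer_only$gene_a, res$cancer_only$gene_b,
                          sep = "\t"), want_co)
  }
})

test_that("intersection is invariant to network argument order", {
  nets <- lapply(1:3, function(i) random_edges(100, 40, seed = i))
  names(nets) <- c("x", "y", "z")
  a <- intersect_networks(nets, control_name = "x")
  b <- intersect_networks(rev(nets), control_name = "x")
  expect_setequal(paste(a$shared_all$gene_a, a$shared_all$gene_b),
                  paste(b$shared_all$gene_a, b$shared_all$gene_b))
  expect_equal(a$totals[sort(names(a$totals))], b$totals[sort(names(b$totals))])
})

test_that("curves hit the trivial bounds for identical and disjoint inputs", {
  e <- random_edges(400, 60, seed = 2)
  cv <- intersection_curve(list(a = e, b = e, c = e), c(10, 100, 300), "a")
  expect_equal(cv$proportion_shared_all, rep(1, 3))
  expect_equal(cv$proportion_cancer_only, rep(0, 3))

  genes <- sprintf("g%03d", 1:40)
  d1 <- mi_edges(rep("g001", 10), genes[2:11], stats::runif(10))
  d2 <- mi_edges(rep("g020", 10), genes[21:30], stats::runif(10))
  d3 <- mi_edges(rep("g031", 9), genes[32:40], stats::runif(9))
  cv2 <- intersection_curve(list(a = d1, b = d2, c = d3), c(3, 9))
  expect_equal(cv2$proportion_shared_all, c(0, 0))
  expect_error(intersection_curve(list(a = d1, b = d2), c(10, 10)),
               "strictly increasing")
})

test_that("proportion shared by all is bounded by pairwise sharing", {
  nets <- lapply(1:4, function(i) random_edges(250, 40, seed = 20 + i))
  names(nets) <- sprintf("n%d", 1:4)
  for (n in c(50, 100, 250)) {
    tops <- lapply(nets, top_n, n = n)
    res <- intersect_networks(tops)
    expect_lte(nrow(res$shared_all), min(res$pairwise_shared))
  }
})

test_that("divergence follows 1 - overlap/size with strict size checking", {
  e <- random_edges(100, 60, seed = 3)
  expect_equal(pairwise_divergence(e, e), 0)
  ks <- paste0("p", 1:20000)
  a <- ks[1:10000]
  b <- c(a[1:260], ks[10001:19740])
  expect_equal(pairwise_divergence(a, b), 0.974, tolerance = 1e-12)
  expect_equal(pairwise_divergence(ks[1:100], ks[101:200]), 1)
  expect_error(pairwise_divergence(ks[1:5], ks[1:6]), "size")
})

test_that("graded shared modules give a falling intersection curve", {
  neg <- 0L
  for (s in 1:6) {
    co <- generate_cohort(intersection_cohort_config(s))
    norm <- normalize_counts(co$counts)
    ph <- attr(co$labels, "phenotype_order")
    nets <- lapply(ph, function(p)
      mi_matrix(norm$normalized, co$labels$sample_id[co$labels$phenotype == p]))
    names(nets) <- ph
    cv <- intersection_curve(nets, c(100L, 300L, 1000L, 3000L, 10000L), "control")
    rho <- stats::cor(cv$cutoff, cv$proportion_shared_all, method = "spearman")
    neg <- neg + (rho < 0)
    expect_true(all(cv$proportion_shared_all >= 0 & cv$proportion_shared_all <= 1))
  }
  expect_gte(neg, 5L)
})
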