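# Broad-expression filter, paired signed-rank DE, CN correlation.

test_that("broad-expression filter bounds are inclusive", {
  mk <- function(n_pass, n = 100) {
    tum <- matrix(rep(c(2, 0.5), c(n_pass, n - n_pass)), nrow = 1)
    colnames(tum) <- sprintf("S%03d-T", 1:n)
    vals <- dplyr::bind_cols(tibble::tibble(gene_id = "G1"),
                             tibble::as_tibble(as.data.frame(tum)))
    meta <- tibble::tibble(sample_id = colnames(tum),
                           patient_id = sprintf("S%03d", 1:n),
                           tissue = "tumour")
    broad_expression_filter(list(values = vals, sample_meta = meta))
  }
  expect_true(mk(95)$broad_expressed)
  expect_false(mk(89)$broad_expressed)
  expect_true(mk(90)$broad_expressed)   # exactly 90% passes
})

test_that("exact signed-rank p matches the enumeration oracle", {
  # the tied worked case: differences (+1,+2,+3,+4,+5,-1)
  d <- c(1, 2, 3, 4, 5, -1)
  res <- omicdriver:::signed_rank_test(d)
  expect_true(res$exact)
  expect_equal(res$p, enum_signed_rank_p(d), tolerance = 1e-12)
  # 100 random paired vectors with n <= 10, including zeros and ties
  set.seed(20)
  for (i in 1:100) {
    n <- sample(3:10, 1)
    d <- round(rnorm(n), sample(c(1, 2), 1))
    if (all(d == 0)) d[1] <- 0.5
    expect_equal(omicdriver:::signed_rank_test(d)$p,
                 enum_signed_rank_p(d), tolerance = 1e-12)
  }
})

test_that("tie-free exact path agrees with stats::wilcox.test", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(5:20, 1)
    d <- rnorm(n)   # continuous: no zeros, no ties
    ours <- omicdriver:::signed_rank_test(d)$p
    ref <- stats::wilcox.test(d, exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("large-n path matches wilcox.test's corrected approximation", {
  set.seed(22)
  for (i in 1:10) {
    d <- rnorm(40, mean = 0.2)
    ours <- omicdriver:::signed_rank_test(d)$p
    ref <- suppressWarnings(
      stats::wilcox.test(d, exact = FALSE, correct = TRUE)$p.value
    )
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("degenerate paired input yields p = 1 and no flag", {
  tum <- matrix(2, nrow = 3, ncol = 12)
  expr <- make_paired_expression(tum, tum)
  de <- paired_wilcoxon_de(expr)
  expect_true(all(de$p == 1))
  expect_false(any(de$de_flag))
  expect_true(all(de$direction == "none"))
})

test_that("insufficient pairs are reported, not silently flagged", {
  tum <- matrix(2, nrow = 2, ncol = 4)
  expr <- make_paired_expression(tum, tum * 2)
  de <- paired_wilcoxon_de(expr, min_pairs = 10)
  expect_false(any(de$de_flag))
  expect_equal(unique(de$reason), "insufficient pairs")
  # no normals at all
  expr2 <- expr
  expr2$sample_meta <- dplyr::filter(expr2$sample_meta,
                                     tissue == "tumour")
  expr2$values <- expr2$values[, c("gene_id",
                                   expr2$sample_meta$sample_id)]
  de2 <- paired_wilcoxon_de(expr2)
  expect_equal(unique(de2$reason), "no matched normals")
})

test_that("a planted shift is recovered with the right direction", {
  set.seed(33)
  n_genes <- 40; n_pairs <- 30
  base <- matrix(2^rnorm(n_genes * n_pairs, 4, 0.5), n_genes)
  tum <- base * 2^matrix(rnorm(n_genes * n_pairs, 0, 0.5), n_genes)
  tum[1, ] <- tum[1, ] * 2^1.5
  expr <- make_paired_expression(tum, base)
  de <- paired_wilcoxon_de(expr)
  expect_true(de$de_flag[1])
  expect_equal(de$direction[1], "up")
  # BH q-values are monotone in p
  ord <- order(de$p)
  expect_true(all(diff(de$q[ord]) >= -1e-12))
})

test_that("Pearson correlation flags positive dosage relationships", {
  genes <- sprintf("G%d", 1:2)
  n <- 20
  cn <- matrix(c(seq(0, 1.5, length.out = n), rep(0.5, n)),
               nrow = 2, byrow = TRUE,
               dimnames = list(genes, sprintf("P%03d-T", 1:n)))
  tum <- rbind(2^(3 + cn[1, ]) , rep(8, n))
  expr <- make_paired_expression(tum, tum, genes = genes)
  corr <- expr_cnv_correlation(expr, make_gene_cn(cn))
  g1 <- corr[corr$gene_id == "G1", ]
  expect_gt(g1$r, 0.999)  # log2(FPKM + 1) is near- but not exactly linear
  expect_true(g1$correlated)
  g2 <- corr[corr$gene_id == "G2", ]
  expect_false(g2$correlated)
  expect_equal(g2$reason, "zero variance")
})

test_that("hand-computed four-point Pearson case is exact", {
  x <- c(0, 0.5, 1, 1.5); y <- c(1, 2, 3, 4)
  ct <- cor.test(x, y)
  expect_equal(unname(ct$estimate), 1, tolerance = 1e-12)
  genes <- "G1"
  cn <- matrix(x, 1, dimnames = list(genes, sprintf("P%03d-T", 1:4)))
  tum <- matrix(y, 1)
  expr <- make_paired_expression(tum, tum, genes = genes)
  # 4 tumour specimens, all with FPKM >= 1: passes the broad filter
  corr <- expr_cnv_correlation(expr, make_gene_cn(cn))
  # log2(y + 1) is not exactly linear in x, but strongly monotone
  expect_gt(corr$r, 0.99)
})

test_that("Pearson r is invariant to positive affine rescaling", {
  set.seed(44)
  x <- rnorm(30); y <- x + rnorm(30, 0, 0.5)
  r1 <- cor(x, y)
  r2 <- cor(2 * x + 3, 0.5 * y - 1)
  expect_equal(r1, r2, tolerance = 1e-12)
})
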