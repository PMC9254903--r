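# Gene-level copy-number mapping, G-scores, permutation q-values and the
# recurrence filter.

test_that("segment-to-gene mapping is a length-weighted mean", {
  genes <- tibble::tibble(
    gene_id = "G1", chrom = "chr1", start = 1001L, end = 2000L,
    strand = "+"
  )
  # fully inside one segment
  seg1 <- tibble::tibble(
    sample_id = "S1", chrom = "chr1", start = 1L, end = 10000L,
    n_markers = 10L, log2_ratio = 0.5
  )
  m1 <- segments_to_gene_matrix(seg1, genes)
  expect_equal(m1$log2_ratio, 0.5)
  # split 60/40 between 0.5 and 0.0: gene 1001..2000, boundary at 1600
  seg2 <- tibble::tibble(
    sample_id = "S1", chrom = "chr1",
    start = c(1L, 1601L), end = c(1600L, 10000L),
    n_markers = 10L, log2_ratio = c(0.5, 0)
  )
  m2 <- segments_to_gene_matrix(seg2, genes)
  expect_equal(m2$log2_ratio, 0.6 * 0.5 + 0.4 * 0, tolerance = 1e-12)
  # all-zero segments -> all-zero matrix
  seg3 <- dplyr::mutate(seg2, log2_ratio = 0)
  expect_true(all(segments_to_gene_matrix(seg3, genes)$log2_ratio == 0))
})

test_that("genes without any segment are imputed to zero and flagged", {
  genes <- tibble::tibble(
    gene_id = c("G1", "G2"), chrom = c("chr1", "chr2"),
    start = c(100L, 100L), end = c(200L, 200L), strand = "+"
  )
  seg <- tibble::tibble(
    sample_id = "S1", chrom = "chr1", start = 1L, end = 1000L,
    n_markers = 1L, log2_ratio = 0.3
  )
  expect_warning(m <- segments_to_gene_matrix(seg, genes), "no segments")
  expect_equal(m$log2_ratio[m$gene_id == "G2"], 0)
  expect_equal(attr(m, "genes_without_segments"), "G2")
  expect_equal(attr(m, "n_imputed"), 1)
})

test_that("G-score matches hand-evaluated frequency x amplitude", {
  cn <- tibble::tibble(
    gene_id = "G1", sample_id = paste0("S", 1:10),
    log2_ratio = c(rep(0.5, 4), rep(0, 6))
  )
  g <- gscore(cn)
  expect_equal(g$g[g$direction == "amp"], 4 * (0.5 - 0.1) / 10)
  expect_equal(g$g[g$direction == "del"], 0)
  cn2 <- dplyr::mutate(
    cn, log2_ratio = c(rep(-0.6, 5), rep(0, 5))
  )
  g2 <- gscore(cn2)
  expect_equal(g2$g[g2$direction == "del"], 5 * (0.6 - 0.1) / 10)
  expect_equal(g2$g[g2$direction == "amp"], 0)
  # all zero -> both zero
  g3 <- gscore(dplyr::mutate(cn, log2_ratio = 0))
  expect_true(all(g3$g == 0))
})

test_that("G-scores are invariant to sample and gene order and monotone", {
  set.seed(11)
  m <- matrix(rnorm(20 * 8, 0, 0.3), 20, 8,
              dimnames = list(sprintf("G%02d", 1:20), paste0("S", 1:8)))
  cn <- make_gene_cn(m)
  g0 <- dplyr::arrange(gscore(cn), gene_id, direction)
  perm <- cn[sample(nrow(cn)), ]
  g1 <- dplyr::arrange(gscore(perm), gene_id, direction)
  expect_equal(g0, g1)
  # doubling amplitudes above the floor strictly increases affected G
  m2 <- ifelse(m > 0.1, m * 2, m)
  g2 <- dplyr::arrange(gscore(make_gene_cn(m2)), gene_id, direction)
  amp0 <- g0$g[g0$direction == "amp"]
  amp2 <- g2$g[g2$direction == "amp"]
  affected <- rowSums(m > 0.1)[order(rownames(m))] > 0
  expect_true(all(amp2[affected] > amp0[affected]))
  expect_equal(amp2[!affected], amp0[!affected])
})

test_that("permutation p-values match the exact pooled-null oracle", {
  set.seed(5)
  m <- matrix(round(rnorm(5 * 4, 0, 0.4), 2), 5, 4,
              dimnames = list(paste0("G", 1:5), paste0("S", 1:4)))
  theta <- 0.1
  cn <- make_gene_cn(m)
  res <- gscore_qvalues(cn, direction = "amp",
                        amplitude_threshold = theta,
                        n_perm = 4000, seed = 3)
  null_exact <- enum_pooled_gscore_null(m, theta, "amp")
  p_exact <- vapply(res$g[match(paste0("G", 1:5), res$gene_id)],
                    function(g) mean(null_exact >= g), numeric(1))
  p_mc <- res$p[match(paste0("G", 1:5), res$gene_id)]
  # Monte-Carlo standard error of a pooled fraction over 5 * 4000 draws
  se <- sqrt(p_exact * (1 - p_exact) / (5 * 4000)) + 1e-3
  expect_true(all(abs(p_mc - p_exact) <= 4 * se))
})

test_that("q-values degenerate correctly and are monotone in G", {
  const <- make_gene_cn(matrix(
    0.5, 4, 6, dimnames = list(paste0("G", 1:4), paste0("S", 1:6))
  ))
  res <- gscore_qvalues(const, n_perm = 100, seed = 1)
  expect_true(all(res$p == 1))
  expect_true(all(res$q == 1))
  set.seed(2)
  m <- matrix(rnorm(30 * 10, 0, 0.3), 30, 10,
              dimnames = list(sprintf("G%02d", 1:30), paste0("S", 1:10)))
  m[1, ] <- m[1, ] + 1  # strong amp
  res2 <- gscore_qvalues(make_gene_cn(m), direction = "amp",
                         n_perm = 200, seed = 4)
  ord <- order(-res2$g)
  expect_true(all(diff(res2$q[ord]) >= -1e-12))
  # zero observed G -> p = 1
  expect_true(all(res2$p[res2$g == 0] == 1))
})

test_that("the recurrence filter applies both thresholds per direction", {
  res <- tibble::tibble(
    gene_id = c("A", "B", "C"), direction = "amp",
    g = c(0.16, 0.09, 0.5), q = c(0.01, 0.001, 0.3), n_samples = 100L
  )
  out <- flag_recurrent(res)
  expect_equal(out$recurrent_amp, c(TRUE, FALSE, FALSE))
  expect_true(all(out$recurrent_del == FALSE))
})

test_that("pan-cancer G-score is the plain per-direction sum", {
  per <- tibble::tibble(
    gene_id = "CHD7", direction = "amp", g = c(0.2, 0.3, 0.0),
    q = 0.1, n_samples = 10L,
    cancer_type = c("C1", "C2", "C3")
  )
  pg <- pan_cancer_gscore(per)
  expect_equal(pg$pan_g[pg$direction == "amp"], 0.5)
  # permuting cancer order changes nothing; single cancer is identity
  pg2 <- pan_cancer_gscore(per[c(3, 1, 2), ])
  expect_equal(pg, pg2)
  expect_equal(pan_cancer_gscore(per[1, ])$pan_g, 0.2)
})

test_that("external SCNA tables are ingested with recomputed flags", {
  tb <- tibble::tibble(
    gene_id = c("CHD7", "CHD7", "CHD5"),
    cancer_type = c("COADREAD", "BRCA", "LUAD"),
    direction = c("amp", "amp", "del"),
    g = c(0.4, 0.4, 0.2), q = c(0.01, 0.01, 0.2),
    in_peak = c(TRUE, FALSE, TRUE)
  )
  out <- ingest_external_scna(tb)
  expect_true(out$recurrent_amp[out$cancer_type == "COADREAD"])
  expect_false(out$recurrent_amp[out$cancer_type == "BRCA"]) # in_peak FALSE
  expect_true(out$recurrent_del[out$cancer_type == "LUAD"])
  expect_error(
    ingest_external_scna(dplyr::select(tb, -q)), "q"
  )
})
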