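# Evidence assembly, CS/PCO scores, conservation and ranking.

# Minimal hand-built stage tables over two genes and two cancer types.
make_stage_tables <- function() {
  key <- tidyr::expand_grid(gene_id = c("CHD7", "CHD5"),
                            cancer_type = c("CRC", "BRCA"))
  scna <- key |>
    dplyr::mutate(
      g_amp = c(0.4, 0, 0, 0), q_amp = c(0.01, 1, 1, 1),
      g_del = c(0, 0, 0.3, 0), q_del = c(1, 1, 0.02, 1),
      recurrent_amp = c(TRUE, FALSE, FALSE, FALSE),
      recurrent_del = c(FALSE, FALSE, TRUE, FALSE),
      n_samples = 100L
    )
  mutation <- key |>
    dplyr::mutate(
      n_mutated_samples = c(8L, 0L, 1L, 0L), n_samples = 100L,
      frequency = c(0.08, 0, 0.01, 0), m_index = c(3L, 0L, 0L, 0L),
      significant = c(TRUE, FALSE, FALSE, FALSE), coverage = "ok"
    )
  fusion <- key |>
    dplyr::mutate(n_events = c(4L, 0L, 0L, 0L),
                  fusion_flag = c(TRUE, FALSE, FALSE, FALSE))
  de <- key |>
    dplyr::mutate(
      n_pairs = c(30L, 0L, 30L, 0L), median_log2fc = c(1.2, NA, 0, NA),
      p = c(1e-5, NA, 0.8, NA), q = c(1e-4, NA, 0.9, NA),
      direction = c("up", "none", "none", "none"),
      de_flag = c(TRUE, FALSE, FALSE, FALSE),
      reason = c("de", "no matched normals", "not significant",
                 "no matched normals")
    )
  survival <- key |>
    dplyr::mutate(
      hr = c(1.1, 1, 0.5, 1), p = c(0.5, 0.9, 0.01, 0.9),
      n = 100L, n_events = 40L,
      prognosis = c("none", "none", "good", "none"),
      evaluable = TRUE, reason = "fitted"
    )
  list(scna = scna, mutation = mutation, fusion = fusion, de = de,
       survival = survival)
}

test_that("the four-condition worked profile scores CS = 4", {
  st <- make_stage_tables()
  flags <- assemble_flags(st$scna, st$mutation, st$fusion, st$de,
                          st$survival)
  cs <- cs_score(flags)
  chd7_crc <- dplyr::filter(cs, gene_id == "CHD7", cancer_type == "CRC")
  expect_equal(chd7_crc$cs, 4L)
  expect_false(chd7_crc$x_surv)
  # no matched normals -> DE condition false with its reason
  chd7_brca <- dplyr::filter(cs, gene_id == "CHD7",
                             cancer_type == "BRCA")
  expect_false(chd7_brca$x_de)
  expect_match(chd7_brca$reason_de, "no matched normals")
})

test_that("CS-score spans 0 to 5 and counts true flags", {
  st <- make_stage_tables()
  flags <- assemble_flags(st$scna, st$mutation, st$fusion, st$de,
                          st$survival)
  all_true <- flags[1, ] |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("x_"), ~TRUE))
  expect_equal(cs_score(all_true)$cs, 5L)
  all_false <- flags[1, ] |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("x_"), ~FALSE))
  expect_equal(cs_score(all_false)$cs, 0L)
})

test_that("PCO is conserved across cancers and channel components", {
  st <- make_stage_tables()
  scores <- score_candidates(st$scna, st$mutation, st$fusion, st$de,
                             st$survival)
  chd7 <- dplyr::filter(scores$pco, gene_id == "CHD7")
  expect_equal(chd7$pco, 4L)   # 4 in CRC + 0 in BRCA
  comp <- scores$components |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(s = sum(count))
  expect_equal(
    comp$s[match(scores$pco$gene_id, comp$gene_id)], scores$pco$pco
  )
  cs_sum <- scores$cs |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(s = sum(cs))
  expect_equal(
    cs_sum$s[match(scores$pco$gene_id, cs_sum$gene_id)], scores$pco$pco
  )
  # single cancer: pco equals cs
  one <- lapply(st, function(x) dplyr::filter(x, cancer_type == "CRC"))
  s1 <- score_candidates(one$scna, one$mutation, one$fusion, one$de,
                         one$survival)
  expect_equal(
    s1$pco$pco[s1$pco$gene_id == "CHD7"],
    s1$cs$cs[s1$cs$gene_id == "CHD7"]
  )
})

test_that("a stage that misses panel genes is a hard error", {
  st <- make_stage_tables()
  expect_error(
    assemble_flags(st$scna, st$mutation[-1, ], st$fusion, st$de,
                   st$survival),
    "mutation.*missing"
  )
})

test_that("ranking uses pco, then max cs, then pan-G, then gene id", {
  pco <- tibble::tibble(
    gene_id = c("A", "B", "C", "D", "E"),
    pco = c(7L, 7L, 2L, 7L, 7L),
    max_cs = c(3L, 4L, 2L, 3L, 3L),
    n_cancer_types = 3L
  )
  pan_g <- tibble::tibble(
    gene_id = c("A", "D", "E"), direction = "amp",
    pan_g = c(0.5, 0.9, 0.5)
  )
  ranked <- rank_candidates(pco, pan_g)
  expect_equal(ranked$gene_id, c("B", "D", "A", "E", "C"))
  # all-zero scores fall back to lexicographic order
  zero <- dplyr::mutate(pco, pco = 0L, max_cs = 0L)
  expect_equal(rank_candidates(zero)$gene_id, sort(pco$gene_id))
})

test_that("flipping any flag true never demotes a gene", {
  st <- make_stage_tables()
  scores <- score_candidates(st$scna, st$mutation, st$fusion, st$de,
                             st$survival)
  base_rank <- scores$pco
  st2 <- st
  st2$survival$prognosis[1] <- "poor"   # CHD7/CRC survival flips on
  scores2 <- score_candidates(st2$scna, st2$mutation, st2$fusion, st2$de,
                              st2$survival)
  expect_gte(
    scores$pco$rank[scores$pco$gene_id == "CHD7"],
    scores2$pco$rank[scores2$pco$gene_id == "CHD7"]
  )
  expect_equal(scores2$cs$cs[scores2$cs$gene_id == "CHD7" &
                               scores2$cs$cancer_type == "CRC"], 5L)
})

test_that("identical stage tables give identical score tables", {
  st <- make_stage_tables()
  a <- score_candidates(st$scna, st$mutation, st$fusion, st$de,
                        st$survival)
  b <- score_candidates(st$scna, st$mutation, st$fusion, st$de,
                        st$survival)
  expect_identical(a$pco, b$pco)
  expect_identical(a$cs, b$cs)
})

test_that("tidiers and plots expose the score table", {
  st <- make_stage_tables()
  scores <- score_candidates(st$scna, st$mutation, st$fusion, st$de,
                             st$survival)
  td <- tidy(scores)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("pco", "rank", "n_scna", "n_surv") %in% names(td)))
  gl <- glance(scores)
  expect_equal(gl$n_genes, 2L)
  expect_equal(gl$max_cs, 4L)
  expect_s3_class(autoplot(scores), "ggplot")
  expect_s3_class(plot_cs_heatmap(scores), "ggplot")
})
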