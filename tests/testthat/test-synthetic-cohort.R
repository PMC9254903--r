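# The cohort simulator: determinism, planted effects, validity.

test_that("identical config and seed reproduce identical bundles", {
  cfg <- tiny_sim_config()
  a <- simulate_cohort(cfg, seed = 123)
  b <- simulate_cohort(cfg, seed = 123)
  expect_identical(a$bundles[[1]]$segments, b$bundles[[1]]$segments)
  expect_identical(a$bundles[[1]]$mutations, b$bundles[[1]]$mutations)
  expect_identical(a$bundles[[1]]$expression$values,
                   b$bundles[[1]]$expression$values)
  expect_identical(a$bundles[[1]]$clinical, b$bundles[[1]]$clinical)
  c <- simulate_cohort(cfg, seed = 124)
  expect_false(identical(a$bundles[[1]]$segments,
                         c$bundles[[1]]$segments))
})

test_that("planted channels are marginal: disabling one leaves others", {
  cfg_full <- tiny_sim_config()
  cfg_noexpr <- tiny_sim_config(
    planted = dplyr::filter(default_planted_drivers(),
                            !channel %in% c("de_up", "de_down"))
  )
  a <- simulate_cohort(cfg_full, seed = 55)
  b <- simulate_cohort(cfg_noexpr, seed = 55)
  expect_identical(a$bundles[[1]]$segments, b$bundles[[1]]$segments)
  expect_identical(a$bundles[[1]]$mutations, b$bundles[[1]]$mutations)
  expect_identical(a$bundles[[1]]$fusions, b$bundles[[1]]$fusions)
  # expression draws are shared: only the shifted genes' values change
  shifted <- c("CHD7", "SMARCA4", "HELLS")  # the de_up/de_down genes
  av <- dplyr::filter(a$bundles[[1]]$expression$values,
                      !gene_id %in% shifted)
  bv <- dplyr::filter(b$bundles[[1]]$expression$values,
                      !gene_id %in% shifted)
  expect_identical(av, bv)
  # survival is tied to expression by construction, so event times may
  # shift with it; censoring draws come from their own stream
  expect_identical(
    a$bundles[[1]]$clinical$sample_id, b$bundles[[1]]$clinical$sample_id
  )
})

test_that("null cohorts carry no planted drivers and quiet segments", {
  cfg <- tiny_sim_config()
  nc <- null_cohort(cfg, seed = 7)
  expect_equal(nrow(nc$truth$planted), 0)
  # background-only log2 ratios stay near diploid (6 sigma bound)
  expect_lt(max(abs(nc$bundles[[1]]$segments$log2_ratio)), 6 * 0.05)
})

test_that("planted SCNA carrier fraction sits in binomial bounds", {
  cfg <- simulation_config(
    n_cancer_types = 1, n_tumour = 200, n_normal_pairs = 10,
    n_decoys = 10,
    planted = tibble::tibble(gene_id = "CHD7", channel = "scna_amp",
                             cancer_type = NA)
  )
  sim <- simulate_cohort(cfg, seed = 31)
  cn <- segments_to_gene_matrix(sim$bundles[[1]]$segments,
                                sim$bundles[[1]]$gene_model)
  chd7 <- dplyr::filter(cn, gene_id == "CHD7")
  carriers <- sum(chd7$log2_ratio > 0.25)   # amplitude ~ N(0.5, 0.1)
  bounds <- qbinom(c(0.005, 0.995), 200, 0.4)
  expect_gte(carriers, bounds[1])
  expect_lte(carriers, bounds[2])
})

test_that("infeasible configurations fail before sampling", {
  expect_error(tiny_sim_config(scna = list(f_amp = 1.4)), "\\[0, 1\\]")
  expect_error(
    tiny_sim_config(planted = tibble::tibble(
      gene_id = "NOT_A_GENE", channel = "mutation", cancer_type = NA
    )),
    "not in panel"
  )
  expect_error(
    tiny_sim_config(planted = tibble::tibble(
      gene_id = "CHD7", channel = "teleportation", cancer_type = NA
    )),
    "unknown planted channel"
  )
  expect_error(
    simulation_config(n_tumour = 10, n_normal_pairs = 20),
    "n_normal_pairs"
  )
  expect_error(
    simulation_config(n_tumour = 3, n_normal_pairs = 2,
                      fusion = list(planted_pair_count = 5)),
    "fusion"
  )
})

test_that("generated tables survive a disk round trip with no repairs", {
  cfg <- tiny_sim_config()
  sim <- simulate_cohort(cfg, seed = 99)
  dir <- withr::local_tempdir()
  write_cohort_dir(sim$bundles[[1]], dir)
  back <- read_cohort_dir(dir, cancer_type = "SIM01")
  expect_equal(io_log(back$segments)$rows_dropped, 0)
  expect_equal(io_log(back$mutations)$rows_dropped, 0)
  expect_equal(
    dplyr::arrange(back$segments, sample_id, chrom, start)$log2_ratio,
    dplyr::arrange(sim$bundles[[1]]$segments, sample_id, chrom,
                   start)$log2_ratio,
    tolerance = 1e-5   # 6 significant digits on disk
  )
  expect_equal(sort(back$mutations$gene_id),
               sort(sim$bundles[[1]]$mutations$gene_id))
})

test_that("the dosage coupling links copy number to expression", {
  cfg <- simulation_config(
    n_cancer_types = 1, n_tumour = 150, n_normal_pairs = 10,
    n_decoys = 10,
    planted = tibble::tibble(gene_id = "CHD7", channel = "scna_amp",
                             cancer_type = NA)
  )
  sim <- simulate_cohort(cfg, seed = 17)
  b <- sim$bundles[[1]]
  cn <- segments_to_gene_matrix(b$segments, b$gene_model)
  corr <- expr_cnv_correlation(b$expression, cn)
  expect_true(corr$correlated[corr$gene_id == "CHD7"])
})

test_that("planted survival effect shows up; null theta is calibrated", {
  cfg <- simulation_config(
    n_cancer_types = 1, n_tumour = 250, n_normal_pairs = 10,
    n_decoys = 10,
    planted = tibble::tibble(gene_id = "HELLS", channel = "prognosis",
                             cancer_type = NA)
  )
  sim <- simulate_cohort(cfg, seed = 13)
  sres <- survival_stage(sim$bundles[[1]])
  expect_true(sres$prognosis[sres$gene_id == "HELLS"] != "none")
  # decoys carry no planted hazard: the planted gene dominates
  decoys <- dplyr::filter(sres, grepl("^DECOY", gene_id))
  expect_lt(sres$p[sres$gene_id == "HELLS"], min(decoys$p))
})

test_that("truth serialization and tidier expose the planted table", {
  cfg <- tiny_sim_config()
  sim <- simulate_cohort(cfg, seed = 3)
  td <- tidy(sim$truth)
  expect_true(all(c("cancer_type", "gene_id", "channel") %in% names(td)))
  expect_setequal(unique(td$gene_id), c("CHD7", "SMARCA4", "HELLS"))
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_json(sim$truth, path)
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(parsed$seed, 3)
  expect_equal(nrow(parsed$planted), nrow(td))
})
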