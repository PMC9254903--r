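# Readers, writers and their accounting invariants.

write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("read_seg parses and normalizes chromosome names", {
  path <- write_lines_tmp(c(
    "Sample\tChromosome\tloc.start\tloc.end\tnum.mark\tseg.mean",
    "S1\t8\t100\t5000\t10\t0.25",
    "S1\tchr9\t100\t5000\t10\t-0.10",
    "S2\tchrX\t100\t5000\t10\t0.00"
  ))
  seg <- read_seg(path)
  expect_equal(nrow(seg), 3)
  expect_setequal(seg$chrom, c("chr8", "chr9", "chrX"))
  expect_equal(io_log(seg)$rows_in, 3)
  expect_equal(io_log(seg)$rows_dropped, 0)
})

test_that("overlapping segments are resolved by keeping the longer one", {
  path <- write_lines_tmp(c(
    "Sample\tChromosome\tloc.start\tloc.end\tnum.mark\tseg.mean",
    "S1\tchr8\t100\t10000\t10\t0.5",   # 9901 bp
    "S1\tchr8\t8000\t9000\t5\t-0.3",   # 1001 bp, nested
    "S2\tchr8\t100\t10000\t10\t0.1"
  ))
  expect_warning(seg <- read_seg(path), "overlap")
  s1 <- seg[seg$sample_id == "S1", ]
  expect_equal(nrow(s1), 1)
  expect_equal(s1$log2_ratio, 0.5)
  log <- io_log(seg)
  expect_equal(log$rows_in, log$rows_kept + log$rows_dropped)
  expect_equal(log$overlaps_resolved, 1)
})

test_that("header-only SEG file gives an empty table, not an error", {
  path <- write_lines_tmp(
    "Sample\tChromosome\tloc.start\tloc.end\tnum.mark\tseg.mean"
  )
  seg <- read_seg(path)
  expect_equal(nrow(seg), 0)
  expect_equal(io_log(seg)$rows_in, 0)
})

test_that("SEG format errors name the offending column or line", {
  path <- write_lines_tmp(c(
    "Sample\tChromosome\tloc.start\tloc.end",
    "S1\tchr8\t100\t5000"
  ))
  expect_error(read_seg(path), "log2_ratio")
  path2 <- write_lines_tmp(c(
    "Sample\tChromosome\tloc.start\tloc.end\tnum.mark\tseg.mean",
    "S1\tchr8\t100\t5000\t10\t0.2",
    "S1\tchr9\t100\t5000\t10\tnot_a_number"
  ))
  expect_error(read_seg(path2), "line.*3|3.*not_a_number")
})

test_that("SEG parsing is insensitive to input row order", {
  lines <- c(
    "S1\tchr8\t100\t5000\t10\t0.25",
    "S2\tchr1\t100\t5000\t10\t-0.5",
    "S1\tchr2\t100\t5000\t10\t0.75"
  )
  header <- "Sample\tChromosome\tloc.start\tloc.end\tnum.mark\tseg.mean"
  a <- read_seg(write_lines_tmp(c(header, lines)))
  b <- read_seg(write_lines_tmp(c(header, rev(lines))))
  expect_equal(
    dplyr::arrange(as.data.frame(a), sample_id, chrom),
    dplyr::arrange(as.data.frame(b), sample_id, chrom)
  )
})

test_that("MAF-lite maps variant classes and excludes silent rows", {
  path <- write_lines_tmp(c(
    "Tumor_Sample_Barcode\tHugo_Symbol\tVariant_Classification",
    "S1\tCHD7\tMissense_Mutation",
    "S1\tCHD7\tSilent",
    "S1\tCHD7\tFrame_Shift_Ins",
    "S2\tCHD5\tSplice_Site"
  ))
  maf <- read_maf_lite(path)
  expect_equal(nrow(maf), 3)
  expect_equal(maf$variant_class[1], "missense")
  expect_equal(io_log(maf)$excluded_silent, 1)
  expect_equal(io_log(maf)$rows_in,
               io_log(maf)$rows_kept + io_log(maf)$rows_dropped)
})

test_that("MAF-lite keeps one record per event and drops unmappables", {
  path <- write_lines_tmp(c(
    "Tumor_Sample_Barcode\tHugo_Symbol\tVariant_Classification",
    "S1\tCHD7\tMissense_Mutation",
    "S1\tCHD7\tMissense_Mutation",     # second event, same gene/sample
    "S1\tCHD7\tTotally_Unknown_Class"
  ))
  expect_warning(maf <- read_maf_lite(path), "unmappable")
  expect_equal(nrow(maf), 2)
  expect_equal(io_log(maf)$unmappable_class, 1)
})

test_that("stage tables are written sorted, rounded, and byte-stable", {
  tb <- tibble::tibble(
    gene_id = c("B", "A", "B", "A"),
    cancer_type = c("C2", "C2", "C1", "C1"),
    value = c(0.123456789, 1 / 3, 2, 0.000012345678)
  )
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_stage_table(tb, f1)
  write_stage_table(tb[sample(4), ], f2)
  expect_identical(readLines(f1), readLines(f2))
  lines <- readLines(f1)
  expect_equal(length(lines), 5)
  expect_match(lines[2], "^A\tC1\t")
  expect_match(lines[3], "^A\tC2\t0\\.333333$")
  # round trip preserves 6 significant digits
  back <- readr::read_tsv(f1, show_col_types = FALSE)
  expect_equal(back$value[back$gene_id == "A" & back$cancer_type == "C2"],
               signif(1 / 3, 6))
  # empty result -> header only
  f3 <- withr::local_tempfile()
  write_stage_table(tb[0, ], f3)
  expect_equal(readLines(f3), "gene_id\tcancer_type\tvalue")
})

test_that("fusion and clinical readers enforce their invariants", {
  bad_fus <- write_lines_tmp(c(
    "sample\tcancer_type\tgene5\tgene3",
    "S1\tCRC\tCHD7\tCHD7"
  ))
  expect_error(read_fusion_table(bad_fus), "self-fusion")
  ok_fus <- write_lines_tmp(c(
    "sample\tcancer_type\tgene5\tgene3",
    "S1\tCRC\tCHD7\tTOX"
  ))
  expect_equal(nrow(read_fusion_table(ok_fus)), 1)
  bad_clin <- write_lines_tmp(c(
    "sample\tOS.time\tOS.event",
    "S1\t-10\t1"
  ))
  expect_error(read_clinical(bad_clin), "os_time")
  bad_clin2 <- write_lines_tmp(c(
    "sample\tOS.time\tOS.event",
    "S1\t100\t2"
  ))
  expect_error(read_clinical(bad_clin2), "os_event")
})

test_that("expression metadata rejects duplicate (patient, tissue) keys", {
  tum <- matrix(1, 2, 2)
  expr <- make_paired_expression(tum, tum)
  expr$sample_meta$patient_id[2] <- expr$sample_meta$patient_id[1]
  expect_error(validate_expression(expr$values, expr$sample_meta),
               "duplicated")
})

test_that("BED gene models round-trip through the 0/1-based conversion", {
  panel <- atpcr_panel()
  path <- withr::local_tempfile(fileext = ".bed")
  write_gene_bed(panel, path)
  back <- read_gene_bed(path)
  expect_equal(as.data.frame(back), as.data.frame(panel))
  # BED start is 0-based: first gene's BED start = internal start - 1
  bed <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  expect_equal(bed[[2]][1], panel$start[1] - 1L)
})
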