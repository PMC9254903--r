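# Readers for the external tabular formats. Every reader returns a tibble
# carrying an "io_log" attribute that accounts for all input rows
# (rows_in = rows_kept + rows_dropped) plus format-specific counters.

set_io_log <- function(df, rows_in, rows_kept, rows_dropped, ...) {
  stopifnot(rows_in == rows_kept + rows_dropped)
  attr(df, "io_log") <- c(
    list(
      rows_in = rows_in, rows_kept = rows_kept, rows_dropped = rows_dropped
    ),
    list(...)
  )
  df
}

#' Retrieve the input-accounting log of a parsed table
#'
#' @param x A tibble returned by one of the `read_*()` functions.
#' @return A named list with at least `rows_in`, `rows_kept`, `rows_dropped`.
#' @export
io_log <- function(x) attr(x, "io_log")

# Resolve a dialect: map canonical column roles onto actual header names,
# matching case-insensitively against common aliases.
resolve_columns <- function(header, aliases, required, what) {
  found <- purrr::map(aliases, function(a) {
    hit <- which(tolower(header) %in% tolower(a))
    if (length(hit) > 0) header[hit[1]] else NA_character_
  })
  missing <- names(found)[vapply(found, is.na, logical(1)) &
    names(found) %in% required]
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing mandatory column(s): %s (accepted aliases: %s)",
      what, paste(missing, collapse = ", "),
      paste(purrr::imap_chr(
        aliases[missing], ~ paste0(.y, " = {", paste(.x, collapse = "|"), "}")
      ), collapse = "; ")
    ))
  }
  found
}

#' Read a SEG file of segmented copy-number profiles
#'
#' Parses the standard tab-delimited SEG format (sample, chromosome, start,
#' end, optional marker count, segment mean as a copy-number log2 ratio).
#' Chromosome names are normalized (with or without a `chr` prefix).
#' Overlapping segments within one sample and chromosome are resolved by
#' keeping the longer segment (the one covering more bases of the conflict
#' region); each resolution is logged and counted.
#'
#' @param path Path to a tab-delimited file with a header.
#' @param dialect Optional named character vector overriding column names,
#'   with names among `sample`, `chrom`, `start`, `end`, `n_markers`,
#'   `log2_ratio`.
#' @return A tibble of validated segment records (`sample_id`, `chrom`,
#'   `start`, `end`, `n_markers`, `log2_ratio`) with an `io_log` attribute.
#' @export
read_seg <- function(path, dialect = NULL) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  aliases <- list(
    sample = c("sample", "id", "sample_id", "samplename"),
    chrom = c("chrom", "chromosome", "chr"),
    start = c("start", "loc.start", "loc_start"),
    end = c("end", "loc.end", "loc_end"),
    n_markers = c("num.mark", "num_mark", "n_markers", "num_probes"),
    log2_ratio = c("seg.mean", "seg_mean", "log2_ratio", "segment_mean")
  )
  if (!is.null(dialect)) {
    for (k in names(dialect)) aliases[[k]] <- dialect[[k]]
  }
  cols <- resolve_columns(
    names(raw), aliases,
    required = c("sample", "chrom", "start", "end", "log2_ratio"),
    what = "SEG file"
  )
  n_in <- nrow(raw)
  if (n_in == 0) {
    out <- tibble(
      sample_id = character(), chrom = character(),
      start = integer(), end = integer(),
      n_markers = integer(), log2_ratio = double()
    )
    return(set_io_log(out, 0L, 0L, 0L, overlaps_resolved = 0L))
  }
  seg_mean_chr <- raw[[cols$log2_ratio]]
  seg_mean <- suppressWarnings(as.numeric(seg_mean_chr))
  bad <- which(is.na(seg_mean) & !is.na(seg_mean_chr))
  if (length(bad) > 0) {
    abort(sprintf(
      "SEG file: non-numeric segment mean at line(s) %s (value(s): %s)",
      paste(bad + 1L, collapse = ", "),
      paste(unique(seg_mean_chr[bad]), collapse = ", ")
    ))
  }
  out <- tibble(
    sample_id = as.character(raw[[cols$sample]]),
    chrom = normalize_chrom(raw[[cols$chrom]]),
    start = as.integer(as.numeric(raw[[cols$start]])),
    end = as.integer(as.numeric(raw[[cols$end]])),
    n_markers = if (!is.na(cols$n_markers)) {
      as.integer(as.numeric(raw[[cols$n_markers]]))
    } else {
      NA_integer_
    },
    log2_ratio = seg_mean
  )
  if (any(out$start >= out$end)) {
    abort(sprintf(
      "SEG file: start >= end at line(s) %s",
      paste(which(out$start >= out$end) + 1L, collapse = ", ")
    ))
  }
  resolved <- resolve_overlaps(out)
  set_io_log(
    resolved$segments, n_in, nrow(resolved$segments),
    n_in - nrow(resolved$segments),
    overlaps_resolved = resolved$n_dropped
  )
}

# Keep the longer of any two overlapping segments within (sample, chrom);
# iterate until clean. Deterministic for any input row order.
resolve_overlaps <- function(segments) {
  seg <- arrange(
    segments, .data$sample_id, .data$chrom, .data$start, .data$end
  )
  n_dropped <- 0L
  repeat {
    seg <- seg |>
      group_by(.data$sample_id, .data$chrom) |>
      mutate(
        .len = .data$end - .data$start + 1L,
        .prev_end = dplyr::lag(.data$end),
        .prev_len = dplyr::lag(.data$.len)
      ) |>
      ungroup()
    clash <- !is.na(seg$.prev_end) & seg$start <= seg$.prev_end
    if (!any(clash)) break
    # for each clashing pair drop the shorter member
    drop <- logical(nrow(seg))
    idx <- which(clash)
    for (i in idx) {
      loser <- if (seg$.len[i] >= seg$.prev_len[i]) i - 1L else i
      drop[loser] <- TRUE
    }
    n_dropped <- n_dropped + sum(drop)
    warn(sprintf(
      "SEG: resolved %d overlapping segment(s) by keeping the longer segment",
      sum(drop)
    ))
    seg <- seg[!drop, ]
  }
  list(
    segments = select(seg, -dplyr::starts_with(".")),
    n_dropped = n_dropped
  )
}

# Documented mapping from MAF Variant_Classification strings onto the
# internal closed enum. Classes mapped to NA are silent/non-coding and are
# excluded from mutation evidence.
maf_class_map <- function() {
  c(
    Missense_Mutation = "missense",
    Nonsense_Mutation = "nonsense",
    Nonstop_Mutation = "nonsense",
    Frame_Shift_Del = "frameshift_indel",
    Frame_Shift_Ins = "frameshift_indel",
    In_Frame_Del = "inframe_indel",
    In_Frame_Ins = "inframe_indel",
    Splice_Site = "splice",
    Splice_Region = "splice",
    Translation_Start_Site = "other",
    De_novo_Start_InFrame = "other",
    De_novo_Start_OutOfFrame = "other",
    Silent = NA_character_,
    Synonymous = NA_character_,
    RNA = NA_character_,
    Intron = NA_character_,
    IGR = NA_character_,
    `3'UTR` = NA_character_,
    `5'UTR` = NA_character_,
    `3'Flank` = NA_character_,
    `5'Flank` = NA_character_
  )
}

#' Read a MAF-lite mutation table
#'
#' Consumes only the sample barcode, gene symbol and variant classification
#' columns of a (possibly full) MAF. Variant classes are mapped onto a closed
#' enum (`missense`, `nonsense`, `frameshift_indel`, `inframe_indel`,
#' `splice`, `other`); silent/synonymous and non-coding rows are excluded and
#' counted, unmappable classes are dropped and counted (never fatal). One row
#' per mutation event: no deduplication happens at parse time.
#'
#' @param path Path to a tab-delimited file with a header.
#' @return A tibble (`sample_id`, `gene_id`, `variant_class`) with an
#'   `io_log` attribute whose counters include `excluded_silent` and
#'   `unmappable_class`.
#' @export
read_maf_lite <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"),
                         comment = "#")
  cols <- resolve_columns(
    names(raw),
    list(
      sample = c("tumor_sample_barcode", "sample", "sample_id"),
      gene = c("hugo_symbol", "gene", "gene_id"),
      class = c("variant_classification", "variant_class")
    ),
    required = c("sample", "gene", "class"),
    what = "MAF-lite file"
  )
  n_in <- nrow(raw)
  map <- maf_class_map()
  cls_raw <- if (n_in > 0) as.character(raw[[cols$class]]) else character()
  mapped <- unname(map[cls_raw])
  known <- cls_raw %in% names(map)
  silent <- known & is.na(mapped)
  unmappable <- !known
  keep <- known & !is.na(mapped)
  if (any(unmappable)) {
    warn(sprintf(
      "MAF-lite: dropped %d row(s) with unmappable variant class: %s",
      sum(unmappable), paste(unique(cls_raw[unmappable]), collapse = ", ")
    ))
  }
  out <- tibble(
    sample_id = as.character(raw[[cols$sample]])[keep],
    gene_id = as.character(raw[[cols$gene]])[keep],
    variant_class = mapped[keep]
  )
  set_io_log(
    out, n_in, sum(keep), n_in - sum(keep),
    excluded_silent = sum(silent), unmappable_class = sum(unmappable)
  )
}

#' Read a fusion event table
#'
#' @param path Tab-delimited file with header columns `sample`,
#'   `cancer_type`, `gene5`, `gene3` (aliases accepted). Self-fusions
#'   (identical 5' and 3' partner) are rejected with an error.
#' @return A tibble (`sample_id`, `cancer_type`, `gene_5p`, `gene_3p`).
#' @export
read_fusion_table <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  cols <- resolve_columns(
    names(raw),
    list(
      sample = c("sample", "sample_id"),
      cancer_type = c("cancer_type", "cancer", "cohort"),
      gene_5p = c("gene5", "gene_5p", "five_prime_gene"),
      gene_3p = c("gene3", "gene_3p", "three_prime_gene")
    ),
    required = c("sample", "cancer_type", "gene_5p", "gene_3p"),
    what = "fusion table"
  )
  out <- tibble(
    sample_id = as.character(raw[[cols$sample]]),
    cancer_type = as.character(raw[[cols$cancer_type]]),
    gene_5p = as.character(raw[[cols$gene_5p]]),
    gene_3p = as.character(raw[[cols$gene_3p]])
  )
  if (any(out$gene_5p == out$gene_3p)) {
    abort("fusion table contains self-fusions (gene_5p == gene_3p)")
  }
  set_io_log(out, nrow(out), nrow(out), 0L)
}

#' Read an expression matrix with its sample metadata
#'
#' The matrix file is genes-by-samples FPKM with a leading `gene_id` column;
#' the metadata file has columns `sample_id`, `tissue` (tumour/normal) and
#' either an explicit `patient_id` column or TCGA-like barcodes from which
#' the patient is derived by truncating at `pair_delim` (keeping
#' `pair_fields` fields). An explicit `patient_id` column always wins.
#'
#' @param path Expression TSV path.
#' @param meta_path Sample metadata TSV path.
#' @param pair_delim,pair_fields Barcode truncation rule used only when no
#'   `patient_id` column is present.
#' @return A list with `values` (tibble, `gene_id` + one column per sample)
#'   and `sample_meta` (tibble `sample_id`, `patient_id`, `tissue`).
#' @export
read_expression_matrix <- function(path, meta_path,
                                   pair_delim = "-", pair_fields = 2L) {
  values <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(values, "gene_id", "expression matrix")
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(.default = "c"))
  require_columns(meta, c("sample_id", "tissue"), "sample metadata")
  if (!"patient_id" %in% names(meta)) {
    meta$patient_id <- vapply(
      strsplit(meta$sample_id, pair_delim, fixed = TRUE),
      function(p) paste(head(p, pair_fields), collapse = pair_delim),
      character(1)
    )
  }
  meta <- select(meta, "sample_id", "patient_id", "tissue")
  validate_expression(values, meta)
  list(values = values, sample_meta = as_tibble(meta))
}

validate_expression <- function(values, sample_meta) {
  samples <- setdiff(names(values), "gene_id")
  if (!all(samples %in% sample_meta$sample_id)) {
    abort(sprintf(
      "expression samples missing from metadata: %s",
      paste(head(setdiff(samples, sample_meta$sample_id), 5), collapse = ", ")
    ))
  }
  if (!all(sample_meta$tissue %in% c("tumour", "normal"))) {
    abort("sample metadata tissue must be 'tumour' or 'normal'")
  }
  key <- paste(sample_meta$patient_id, sample_meta$tissue)
  if (anyDuplicated(key)) {
    abort("duplicated (patient_id, tissue) keys in sample metadata")
  }
  vals <- as.matrix(values[, samples, drop = FALSE])
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("expression values must be finite and non-negative (FPKM)")
  }
  invisible(TRUE)
}

#' Read a clinical overall-survival table
#'
#' @param path Tab-delimited file with columns `sample_id` (alias `sample`),
#'   `OS.time` (days, > 0) and `OS.event` (0/1); aliases `os_time`,
#'   `os_event` accepted.
#' @return A tibble (`sample_id`, `os_time`, `os_event`).
#' @export
read_clinical <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  cols <- resolve_columns(
    names(raw),
    list(
      sample = c("sample", "sample_id"),
      os_time = c("os.time", "os_time", "time"),
      os_event = c("os.event", "os_event", "event", "status")
    ),
    required = c("sample", "os_time", "os_event"),
    what = "clinical table"
  )
  out <- tibble(
    sample_id = as.character(raw[[cols$sample]]),
    os_time = as.numeric(raw[[cols$os_time]]),
    os_event = as.integer(raw[[cols$os_event]])
  )
  if (any(!is.finite(out$os_time)) || any(out$os_time <= 0)) {
    abort("clinical table: os_time must be finite and > 0")
  }
  if (!all(out$os_event %in% c(0L, 1L))) {
    abort("clinical table: os_event must be 0 or 1")
  }
  set_io_log(out, nrow(out), nrow(out), 0L)
}

#' Read an external driver-call matrix
#'
#' Boolean gene-by-algorithm table as emitted by running external
#' driver-detection algorithms (at most five columns besides `gene_id`).
#' A missing algorithm is an absent column, never a column of `FALSE`.
#'
#' @param path Tab-delimited file with a `gene_id` column and one logical
#'   (or 0/1) column per algorithm.
#' @return A tibble with `gene_id` and logical algorithm columns.
#' @export
read_driver_calls <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(raw, "gene_id", "driver-call matrix")
  algs <- setdiff(names(raw), "gene_id")
  if (length(algs) == 0) abort("driver-call matrix has no algorithm columns")
  if (length(algs) > 5) {
    abort("driver-call matrix has more than 5 algorithm columns")
  }
  if (anyDuplicated(tolower(algs))) {
    abort("driver-call matrix has duplicated algorithm columns")
  }
  out <- mutate(raw, across(dplyr::all_of(algs), as.logical))
  if (any(is.na(as.matrix(out[, algs])))) {
    abort("driver-call matrix entries must be logical or 0/1")
  }
  as_tibble(out)
}
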