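# Gene panel and genome layout.

# Approximate chromosome lengths (bp, GRCh38 scale) used by the simulator
# to lay out background segments and decoy genes.
chrom_lengths <- function() {
  c(
    chr1 = 248e6, chr2 = 242e6, chr3 = 198e6, chr4 = 190e6, chr5 = 181e6,
    chr6 = 171e6, chr7 = 159e6, chr8 = 145e6, chr9 = 138e6, chr10 = 134e6,
    chr11 = 135e6, chr12 = 133e6, chr13 = 114e6, chr14 = 107e6,
    chr15 = 102e6, chr16 = 90e6, chr17 = 83e6, chr18 = 80e6, chr19 = 59e6,
    chr20 = 64e6, chr21 = 47e6, chr22 = 51e6, chrX = 156e6
  )
}

#' The built-in 37-gene ATP-dependent chromatin remodeller panel
#'
#' Returns the default scoring panel: the 37 genes encoding ATP-dependent
#' chromatin remodellers (and remodeller-complex actin subunits) in mammals,
#' spanning the SWI/SNF, ISWI, INO80 and CHD families. Coordinates are
#' approximate (GRCh38, rounded to gene-locus scale); they position genes for
#' segment-to-gene mapping and simulation and are not a substitute for a
#' curated annotation. Any other panel can be supplied as a BED file via
#' [read_gene_bed()] or as a tibble with the same columns.
#'
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (1-based inclusive coordinates).
#' @export
#' @examples
#' atpcr_panel()
atpcr_panel <- function() {
  g <- tibble::tribble(
    ~gene_id,   ~chrom,  ~start_mb,
    "ACTB",     "chr7",    5.53,
    "ACTL6A",   "chr3",  179.28,
    "ACTL6B",   "chr7",  100.24,
    "ACTR5",    "chr20",  38.76,
    "ACTR8",    "chr3",   53.80,
    "ATRX",     "chrX",   77.50,
    "BTAF1",    "chr10",  91.90,
    "CHD1",     "chr5",   98.80,
    "CHD1L",    "chr1",  147.20,
    "CHD2",     "chr15",  92.90,
    "CHD3",     "chr17",   7.90,
    "CHD4",     "chr12",   6.60,
    "CHD5",     "chr1",    6.10,
    "CHD6",     "chr20",  41.40,
    "CHD7",     "chr8",   60.70,
    "CHD8",     "chr14",  21.40,
    "CHD9",     "chr16",  53.00,
    "EP400",    "chr12", 131.90,
    "ERCC6",    "chr10",  49.50,
    "ERCC6L",   "chrX",   72.00,
    "ERCC6L2",  "chr9",   95.60,
    "HELLS",    "chr10",  94.50,
    "HLTF",     "chr3",  149.00,
    "INO80",    "chr15",  40.90,
    "RAD54B",   "chr8",   94.30,
    "RAD54L",   "chr1",   46.20,
    "RAD54L2",  "chr3",   51.60,
    "SHPRH",    "chr6",  145.90,
    "SMARCA1",  "chrX",  129.50,
    "SMARCA2",  "chr9",    2.00,
    "SMARCA4",  "chr19",  10.96,
    "SMARCA5",  "chr4",  143.50,
    "SMARCAD1", "chr4",   94.20,
    "SMARCAL1", "chr2",  216.40,
    "SRCAP",    "chr16",  30.70,
    "TTF2",     "chr1",  117.10,
    "ZRANB3",   "chr2",  135.10
  )
  tibble(
    gene_id = g$gene_id,
    chrom = g$chrom,
    start = as.integer(round(g$start_mb * 1e6)) + 1L,
    end = as.integer(round(g$start_mb * 1e6)) + 150000L,
    strand = "+"
  )
}

#' Validate a gene panel
#'
#' Checks the panel invariants: required columns, `start < end`, unique
#' `gene_id`, strand in `{+, -}`.
#'
#' @param panel A tibble with columns `gene_id`, `chrom`, `start`, `end`
#'   and optionally `strand`.
#' @return The validated panel (invisibly usable in pipes), with normalized
#'   chromosome names.
#' @export
validate_gene_model <- function(panel) {
  require_columns(panel, c("gene_id", "chrom", "start", "end"), "gene panel")
  if (!"strand" %in% names(panel)) panel$strand <- "+"
  if (anyDuplicated(panel$gene_id)) {
    dup <- unique(panel$gene_id[duplicated(panel$gene_id)])
    abort(sprintf(
      "duplicated gene_id in panel: %s", paste(dup, collapse = ", ")
    ))
  }
  if (any(panel$start >= panel$end)) {
    abort("gene panel has records with start >= end")
  }
  if (!all(panel$strand %in% c("+", "-"))) {
    abort("gene panel strand must be '+' or '-'")
  }
  panel$chrom <- normalize_chrom(panel$chrom)
  as_tibble(panel)
}

#' Read a gene model from a BED file
#'
#' Reads a BED6 (or BED4) file into the internal 1-based inclusive gene
#' model: BED's 0-based half-open starts are shifted by +1 on read.
#'
#' @param path Path to a tab-delimited BED file without header.
#' @return A validated gene panel tibble.
#' @export
read_gene_bed <- function(path) {
  bed <- readr::read_tsv(
    path,
    col_names = FALSE, show_col_types = FALSE, progress = FALSE
  )
  if (ncol(bed) < 4) {
    abort("BED gene model needs at least 4 columns (chrom, start, end, name)")
  }
  panel <- tibble(
    gene_id = as.character(bed[[4]]),
    chrom = normalize_chrom(bed[[1]]),
    start = as.integer(bed[[2]]) + 1L,
    end = as.integer(bed[[3]]),
    strand = if (ncol(bed) >= 6) as.character(bed[[6]]) else "+"
  )
  validate_gene_model(panel)
}

#' Write a gene model to BED6
#'
#' Inverse of [read_gene_bed()]: internal 1-based inclusive coordinates are
#' converted back to BED's 0-based half-open convention.
#'
#' @param panel A validated gene panel tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(panel, path) {
  panel <- validate_gene_model(panel)
  bed <- tibble(
    chrom = panel$chrom,
    start = panel$start - 1L,
    end = panel$end,
    name = panel$gene_id,
    score = 0L,
    strand = panel$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

# Deterministic decoy gene layout: `n` decoy genes tiled across autosomes,
# spaced away from panel genes so planted focal events never overlap decoys.
decoy_genes <- function(n, panel, width = 100000L) {
  lens <- chrom_lengths()
  chroms <- names(lens)[names(lens) != "chrX"]
  per_chrom <- ceiling(1.5 * n / length(chroms)) + 1L
  rows <- purrr::map(chroms, function(ch) {
    len <- lens[[ch]]
    starts <- round(seq(10e6, len - 10e6, length.out = per_chrom))
    tibble(
      chrom = ch,
      start = as.integer(starts),
      end = as.integer(starts) + width - 1L
    )
  })
  decoys <- bind_rows(rows)
  # drop decoys that collide with a panel gene locus (within 6 Mb, the
  # maximal focal-event footprint)
  panel <- validate_gene_model(panel)
  collide <- purrr::map_lgl(seq_len(nrow(decoys)), function(i) {
    any(panel$chrom == decoys$chrom[i] &
      panel$start - 6e6 < decoys$end[i] &
      panel$end + 6e6 > decoys$start[i])
  })
  decoys <- decoys[!collide, ][seq_len(n), ]
  if (any(is.na(decoys$start))) {
    abort("cannot lay out that many decoy genes; reduce n_decoys")
  }
  tibble(
    gene_id = sprintf("DECOY%03d", seq_len(n)),
    chrom = decoys$chrom,
    start = decoys$start,
    end = decoys$end,
    strand = "+"
  )
}
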