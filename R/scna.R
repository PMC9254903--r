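# Focal SCNA recurrence evidence: gene-level copy-number matrix, the
# simplified frequency-x-amplitude G-score with a permutation null
# ("GISTIC-lite"), the recurrence filter, the pan-cancer G-score summation,
# and an ingestion path for externally computed GISTIC-style tables.

#' Map copy-number segments onto a gene-level matrix
#'
#' The value for gene g in sample s is the length-weighted mean log2 copy
#' ratio of the segments overlapping g in s. Gene/sample combinations with
#' no overlapping segment are set to 0 (diploid) and counted as imputed;
#' genes on chromosomes absent from all segments get an all-zero row and a
#' warning.
#'
#' @param segments Segment tibble (from [read_seg()] or the simulator).
#' @param gene_model Gene panel tibble.
#' @param samples Optional character vector fixing the sample universe
#'   (defaults to the samples present in `segments`).
#' @return A long tibble (`gene_id`, `sample_id`, `log2_ratio`) covering
#'   every gene-sample combination, with attributes `n_imputed` and
#'   `genes_without_segments`.
#' @export
segments_to_gene_matrix <- function(segments, gene_model, samples = NULL) {
  gene_model <- validate_gene_model(gene_model)
  if (is.null(samples)) samples <- sort(unique(segments$sample_id))
  if (length(samples) == 0) abort("no samples in segment table")
  genes <- select(gene_model, "gene_id", "chrom",
                  g_start = "start", g_end = "end")
  hits <- inner_join(
    as_tibble(segments), genes,
    by = "chrom", relationship = "many-to-many"
  ) |>
    filter(.data$start <= .data$g_end, .data$end >= .data$g_start) |>
    mutate(weight = pmin(.data$end, .data$g_end) -
             pmax(.data$start, .data$g_start) + 1)
  # length-weighted mean per (gene, sample), vectorized via rowsum()
  key <- paste(hits$gene_id, hits$sample_id, sep = "\r")
  num <- rowsum(hits$log2_ratio * hits$weight, key)
  den <- rowsum(hits$weight, key)
  val <- setNames(num[, 1] / den[, 1], rownames(num))
  grid <- tidyr::expand_grid(
    gene_id = gene_model$gene_id, sample_id = samples
  )
  out <- mutate(
    grid,
    log2_ratio = unname(val[paste(.data$gene_id, .data$sample_id,
                                  sep = "\r")])
  )
  n_imputed <- sum(is.na(out$log2_ratio))
  out$log2_ratio[is.na(out$log2_ratio)] <- 0
  no_seg <- setdiff(gene_model$chrom, unique(segments$chrom))
  orphan <- gene_model$gene_id[gene_model$chrom %in% no_seg]
  if (length(orphan) > 0) {
    warn(sprintf(
      "%d gene(s) lie on chromosomes with no segments; all-zero rows: %s",
      length(orphan), paste(head(orphan, 5), collapse = ", ")
    ))
  }
  attr(out, "n_imputed") <- n_imputed
  attr(out, "genes_without_segments") <- orphan
  out
}

# Long gene-CN tibble -> genes x samples matrix.
as_cn_matrix <- function(gene_cn) {
  wide <- tidyr::pivot_wider(
    gene_cn,
    id_cols = "gene_id", names_from = "sample_id", values_from = "log2_ratio"
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$gene_id
  m
}

#' Per-gene recurrence G-scores (frequency x amplitude)
#'
#' For each gene, the amplification score is the per-sample mean exceedance
#' of the copy-ratio above the amplitude floor,
#' `G_amp(g) = mean_s max(0, x_gs - theta)`, and symmetrically
#' `G_del(g) = mean_s max(0, -x_gs - theta)`. Both are non-negative and
#' combine alteration frequency with amplitude, in the spirit of the GISTIC
#' recurrence score but at gene rather than marker resolution.
#'
#' @param gene_cn Long gene-CN tibble from [segments_to_gene_matrix()].
#' @param direction `"amp"`, `"del"` or both (default).
#' @param amplitude_threshold Amplitude floor `theta` (> 0, default 0.1).
#' @return A tibble (`gene_id`, `direction`, `g`, `n_samples`).
#' @export
#' @examples
#' cn <- tibble::tibble(
#'   gene_id = "G1", sample_id = paste0("S", 1:10),
#'   log2_ratio = c(rep(0.5, 4), rep(0, 6))
#' )
#' gscore(cn) # G_amp = 4 * 0.4 / 10 = 0.16
gscore <- function(gene_cn, direction = c("amp", "del"),
                   amplitude_threshold = 0.1) {
  direction <- match.arg(direction, several.ok = TRUE)
  stopifnot(amplitude_threshold > 0)
  m <- as_cn_matrix(gene_cn)
  if (ncol(m) == 0) abort("G-score needs at least one sample")
  purrr::map(direction, function(d) {
    x <- if (d == "amp") m else -m
    tibble(
      gene_id = rownames(m),
      direction = d,
      g = unname(rowMeans(pmax(x - amplitude_threshold, 0))),
      n_samples = ncol(m)
    )
  }) |> bind_rows()
}

#' Permutation q-values for G-scores
#'
#' The null is built by independently permuting each sample's gene-value
#' vector across genes (`n_perm` times); each gene's p-value is the fraction
#' of null G-scores, pooled across genes and permutations, at or above its
#' observed score. Pooling stabilizes the tail for small panels. q-values
#' are Benjamini-Hochberg over the panel and are monotone non-increasing in
#' the observed G within a run.
#'
#' @inheritParams gscore
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed for the permutation stream.
#' @return A tibble (`gene_id`, `direction`, `g`, `p`, `q`, `n_samples`).
#' @export
gscore_qvalues <- function(gene_cn, direction = c("amp", "del"),
                           amplitude_threshold = 0.1,
                           n_perm = 500, seed = 1L) {
  direction <- match.arg(direction, several.ok = TRUE)
  if (n_perm < 100) abort("n_perm must be >= 100")
  m <- as_cn_matrix(gene_cn)
  n_genes <- nrow(m)
  obs <- gscore(gene_cn, direction, amplitude_threshold)
  # precompute exceedances once; permuting values within a column is the
  # same as permuting their exceedances
  e_amp <- if ("amp" %in% direction) pmax(m - amplitude_threshold, 0)
  e_del <- if ("del" %in% direction) pmax(-m - amplitude_threshold, 0)
  ns <- ncol(m)
  col_offset <- rep.int((seq_len(ns) - 1L) * n_genes, rep.int(n_genes, ns))
  null_g <- withr::with_seed(child_seed(seed, "gscore-perm"), {
    purrr::map(seq_len(n_perm), function(b) {
      idx <- col_offset + as.integer(
        vapply(seq_len(ns), function(s) sample.int(n_genes),
               integer(n_genes))
      )
      out <- list()
      if ("amp" %in% direction) {
        out$amp <- rowMeans(matrix(e_amp[idx], nrow = n_genes))
      }
      if ("del" %in% direction) {
        out$del <- rowMeans(matrix(e_del[idx], nrow = n_genes))
      }
      out
    })
  })
  res <- purrr::map(direction, function(d) {
    pool <- sort(unlist(purrr::map(null_g, d), use.names = FALSE))
    o <- filter(obs, .data$direction == d)
    # p = fraction of pooled null >= observed (ties count)
    n_lt <- findInterval(o$g, pool, left.open = TRUE)
    o$p <- (length(pool) - n_lt) / length(pool)
    o$q <- bh_adjust(o$p)
    o
  }) |> bind_rows()
  select(res, "gene_id", "direction", "g", "p", "q", "n_samples")
}

#' Apply the recurrence filter to per-gene SCNA scores
#'
#' A gene is recurrently altered in a direction when its q-value is at or
#' below `q_max` and its G-score at or above `g_min` (defaults 0.25 and
#' 0.1). The SCNA evidence flag used for scoring is
#' `recurrent_amp | recurrent_del`.
#'
#' @param results Tibble from [gscore_qvalues()] (long, per direction), or
#'   any tibble with `gene_id`, `direction`, `g`, `q`.
#' @param q_max,g_min Filter thresholds.
#' @param cancer_type Optional label stamped onto the result.
#' @return A per-gene tibble (`gene_id`, `cancer_type`, `g_amp`, `g_del`,
#'   `q_amp`, `q_del`, `recurrent_amp`, `recurrent_del`, `n_samples`).
#' @export
flag_recurrent <- function(results, q_max = 0.25, g_min = 0.1,
                           cancer_type = NA_character_) {
  require_columns(results, c("gene_id", "direction", "g", "q"),
                  "SCNA results")
  wide <- results |>
    mutate(recurrent = .data$q <= q_max & .data$g >= g_min) |>
    tidyr::pivot_wider(
      id_cols = dplyr::any_of(c("gene_id", "n_samples")),
      names_from = "direction",
      values_from = c("g", "q", "recurrent"),
      names_glue = "{.value}_{direction}"
    )
  for (col in c("g_amp", "g_del")) {
    if (!col %in% names(wide)) wide[[col]] <- 0
  }
  for (col in c("q_amp", "q_del")) {
    if (!col %in% names(wide)) wide[[col]] <- 1
  }
  for (col in c("recurrent_amp", "recurrent_del")) {
    if (!col %in% names(wide)) wide[[col]] <- FALSE
  }
  wide |>
    mutate(cancer_type = cancer_type) |>
    select("gene_id", "cancer_type", "g_amp", "g_del", "q_amp", "q_del",
           "recurrent_amp", "recurrent_del", dplyr::any_of("n_samples"))
}

#' Pan-cancer G-score by unweighted summation
#'
#' Sums each gene's per-cancer G-scores over all cancer types, separately
#' per direction.
#'
#' @param per_cancer_results A tibble binding the per-cancer outputs of
#'   [flag_recurrent()] (wide) or [gscore_qvalues()] (long).
#' @return A tibble (`gene_id`, `direction`, `pan_g`).
#' @export
pan_cancer_gscore <- function(per_cancer_results) {
  df <- as_tibble(per_cancer_results)
  if (!"direction" %in% names(df)) {
    df <- tidyr::pivot_longer(
      df, dplyr::all_of(c("g_amp", "g_del")),
      names_to = "direction", names_prefix = "g_", values_to = "g"
    )
  }
  df |>
    group_by(.data$gene_id, .data$direction) |>
    summarise(pan_g = sum(.data$g), .groups = "drop") |>
    arrange(.data$gene_id, .data$direction)
}

#' Ingest an externally computed SCNA score table
#'
#' Pass-through path for real GISTIC outputs: a TSV (or tibble) with
#' columns `gene_id`, `cancer_type`, `direction` (amp/del), `g`, `q` and an
#' optional logical `in_peak` column. Recurrence flags are recomputed with
#' the same thresholds as the self-contained mode; when `in_peak` is
#' present it is ANDed into the flag.
#'
#' @param table Path to a TSV or a tibble.
#' @param q_max,g_min Filter thresholds (defaults 0.25 / 0.1).
#' @return A per-gene, per-cancer tibble in the [flag_recurrent()] layout,
#'   with `mode = "ingest"` provenance.
#' @export
ingest_external_scna <- function(table, q_max = 0.25, g_min = 0.1) {
  df <- if (is.character(table)) {
    readr::read_tsv(table, show_col_types = FALSE, progress = FALSE)
  } else {
    as_tibble(table)
  }
  require_columns(df, c("gene_id", "cancer_type", "direction", "g", "q"),
                  "external SCNA table")
  if (!all(df$direction %in% c("amp", "del"))) {
    abort("external SCNA table: direction must be 'amp' or 'del'")
  }
  if (!is.numeric(df$g) || !is.numeric(df$q)) {
    abort("external SCNA table: g and q must be numeric")
  }
  has_peak <- "in_peak" %in% names(df)
  df <- mutate(
    df,
    recurrent = .data$q <= q_max & .data$g >= g_min &
      (if (has_peak) as.logical(.data$in_peak) else TRUE)
  )
  out <- df |>
    tidyr::pivot_wider(
      id_cols = c("gene_id", "cancer_type"),
      names_from = "direction",
      values_from = c("g", "q", "recurrent"),
      names_glue = "{.value}_{direction}",
      values_fill = list(g = 0, q = 1, recurrent = FALSE)
    )
  for (col in c("g_amp", "g_del")) if (!col %in% names(out)) out[[col]] <- 0
  for (col in c("q_amp", "q_del")) if (!col %in% names(out)) out[[col]] <- 1
  for (col in c("recurrent_amp", "recurrent_del")) {
    if (!col %in% names(out)) out[[col]] <- FALSE
  }
  out <- select(out, "gene_id", "cancer_type", "g_amp", "g_del", "q_amp",
                "q_del", "recurrent_amp", "recurrent_del")
  attr(out, "mode") <- "ingest"
  out
}

#' Run the full SCNA stage on one cohort bundle
#'
#' Segments-to-genes mapping, G-scores, permutation q-values and the
#' recurrence filter, in one call.
#'
#' @param bundle A `cohort_bundle`.
#' @param q_max,g_min,amplitude_threshold,n_perm Stage parameters.
#' @param seed Integer seed for the permutation stream.
#' @return The [flag_recurrent()] result with `mode = "lite"` provenance.
#' @export
scna_stage <- function(bundle, q_max = 0.25, g_min = 0.1,
                       amplitude_threshold = 0.1, n_perm = 500, seed = 1L) {
  gene_cn <- segments_to_gene_matrix(
    bundle$segments, bundle$gene_model, samples = tumour_samples(bundle)
  )
  res <- gscore_qvalues(
    gene_cn,
    amplitude_threshold = amplitude_threshold,
    n_perm = n_perm, seed = child_seed(seed, "scna", bundle$cancer_type)
  )
  out <- flag_recurrent(res, q_max = q_max, g_min = g_min,
                        cancer_type = bundle$cancer_type)
  attr(out, "mode") <- "lite"
  attr(out, "gene_cn") <- gene_cn
  out
}
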