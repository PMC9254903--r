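# Fusion evidence: event counting per gene and per ordered 5'-3' pair, and
# the recurrence definition (a pair observed at least twice across all
# cancer specimens; per-gene recurrence within a cancer type as the default
# scoring condition).

#' Count fusion events per gene and per gene pair
#'
#' A gene's event count includes every event in which it appears as either
#' the 5' or the 3' partner; pair counts are over ordered (5' -> 3') pairs
#' and are accumulated pan-cancer. A pair is recurrent when observed at
#' least `r_min` times across all specimens. Setting `ordered = FALSE`
#' collapses pairs orientation-blind.
#'
#' @param fusions Fusion tibble (`sample_id`, `cancer_type`, `gene_5p`,
#'   `gene_3p`).
#' @param panel Optional gene panel (tibble or character vector) restricting
#'   the per-gene summary; pair counts keep all partners.
#' @param r_min Recurrence threshold (default 2).
#' @param ordered Treat pairs as ordered 5' -> 3' (default TRUE).
#' @return An object of class `fusion_summary`: a list with `gene_events`
#'   (per gene per cancer), `pair_events` (pan-cancer, with
#'   `recurrent_pair`), `r_min`, `ordered`.
#' @export
count_fusions <- function(fusions, panel = NULL, r_min = 2L,
                          ordered = TRUE) {
  fus <- as_tibble(fusions)
  require_columns(fus, c("sample_id", "cancer_type", "gene_5p", "gene_3p"),
                  "fusion table")
  if (!ordered) {
    swap <- fus$gene_5p > fus$gene_3p
    tmp <- fus$gene_5p[swap]
    fus$gene_5p[swap] <- fus$gene_3p[swap]
    fus$gene_3p[swap] <- tmp
  }
  genes <- if (is.null(panel)) {
    sort(unique(c(fus$gene_5p, fus$gene_3p)))
  } else if (is.data.frame(panel)) {
    panel$gene_id
  } else {
    panel
  }
  long <- bind_rows(
    select(fus, "sample_id", "cancer_type", gene_id = "gene_5p"),
    select(fus, "sample_id", "cancer_type", gene_id = "gene_3p")
  )
  gene_events <- tidyr::expand_grid(
    gene_id = genes, cancer_type = sort(unique(fus$cancer_type))
  ) |>
    left_join(
      count(long, .data$gene_id, .data$cancer_type, name = "n_events"),
      by = c("gene_id", "cancer_type")
    ) |>
    mutate(n_events = dplyr::coalesce(.data$n_events, 0L))
  pair_events <- fus |>
    count(.data$gene_5p, .data$gene_3p, name = "n_events_pan_cancer") |>
    mutate(recurrent_pair = .data$n_events_pan_cancer >= r_min) |>
    arrange(.data$gene_5p, .data$gene_3p)
  structure(
    list(
      gene_events = gene_events,
      pair_events = pair_events,
      genes = genes,
      r_min = r_min,
      ordered = ordered
    ),
    class = "fusion_summary"
  )
}

#' @export
print.fusion_summary <- function(x, ...) {
  cat(sprintf(
    "<fusion_summary> %d gene(s), %d pair(s), %d recurrent pair(s) (r_min = %d, %s pairs)\n",
    dplyr::n_distinct(x$gene_events$gene_id), nrow(x$pair_events),
    sum(x$pair_events$recurrent_pair), x$r_min,
    if (x$ordered) "ordered" else "unordered"
  ))
  invisible(x)
}

#' Per-gene fusion evidence flag for one cancer type
#'
#' Two interpretations of the recurrence condition are available:
#' `within_cancer` (default) flags a gene with at least `r_min` events
#' within that cancer type; `pan_cancer_pair` flags a gene with at least
#' one event in that cancer type that also participates in a pan-cancer
#' recurrent pair.
#'
#' @param summary A `fusion_summary` from [count_fusions()].
#' @param cancer_type Cancer type to evaluate.
#' @param mode `"within_cancer"` or `"pan_cancer_pair"`.
#' @return A tibble (`gene_id`, `cancer_type`, `n_events`, `fusion_flag`).
#' @export
fusion_evidence_flag <- function(summary, cancer_type,
                                 mode = c("within_cancer",
                                          "pan_cancer_pair")) {
  if (!inherits(summary, "fusion_summary")) {
    abort("`summary` must come from count_fusions()")
  }
  mode <- match.arg(mode)
  ge <- filter(summary$gene_events, .data$cancer_type == .env$cancer_type)
  if (nrow(ge) == 0) {
    ge <- tibble(
      gene_id = summary$genes,
      cancer_type = cancer_type, n_events = 0L
    )
  }
  if (mode == "within_cancer") {
    ge$fusion_flag <- ge$n_events >= summary$r_min
  } else {
    rec <- filter(summary$pair_events, .data$recurrent_pair)
    rec_genes <- unique(c(rec$gene_5p, rec$gene_3p))
    ge$fusion_flag <- ge$n_events >= 1L & ge$gene_id %in% rec_genes
  }
  select(ge, "gene_id", "cancer_type", "n_events", "fusion_flag")
}

#' Run the full fusion stage on one cohort bundle
#'
#' @param bundle A `cohort_bundle`.
#' @param r_min Recurrence threshold.
#' @param mode Flag interpretation, see [fusion_evidence_flag()].
#' @param ordered Ordered 5' -> 3' pairs (default TRUE).
#' @return The per-gene flag tibble with the pair table as attribute
#'   `pair_events`.
#' @export
fusion_stage <- function(bundle, r_min = 2L, mode = "within_cancer",
                         ordered = TRUE) {
  fus <- bundle$fusions
  if (!"cancer_type" %in% names(fus)) fus$cancer_type <- bundle$cancer_type
  summary <- count_fusions(fus, panel = bundle$gene_model, r_min = r_min,
                           ordered = ordered)
  out <- fusion_evidence_flag(summary, bundle$cancer_type, mode = mode)
  attr(out, "pair_events") <- summary$pair_events
  out
}
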