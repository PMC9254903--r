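# broom-style tidiers for the package's result objects.

#' Tidy a score table
#'
#' One row per gene: PCO-score, rank, maximum single-cancer CS-score and
#' the per-channel decomposition as columns.
#'
#' @param x A `score_table` from [score_candidates()] or [run_cohorts()].
#' @param ... Unused.
#' @return A tibble ordered by rank.
#' @export
tidy.score_table <- function(x, ...) {
  comp <- tidyr::pivot_wider(
    x$components,
    id_cols = "gene_id", names_from = "channel", values_from = "count",
    names_prefix = "n_"
  )
  x$pco |>
    left_join(comp, by = "gene_id") |>
    arrange(.data$rank)
}

#' Summarise a score table in one row
#'
#' @inheritParams tidy.score_table
#' @return A one-row tibble (`n_genes`, `n_cancer_types`, `max_cs`,
#'   `max_pco`, `n_pco_gt0`).
#' @export
glance.score_table <- function(x, ...) {
  tibble(
    n_genes = dplyr::n_distinct(x$cs$gene_id),
    n_cancer_types = dplyr::n_distinct(x$cs$cancer_type),
    max_cs = max(x$cs$cs),
    max_pco = max(x$pco$pco),
    n_pco_gt0 = sum(x$pco$pco > 0)
  )
}

#' @rdname tidy.score_table
#' @export
tidy.pipeline_result <- function(x, ...) tidy(x$scores, ...)

#' @rdname glance.score_table
#' @export
glance.pipeline_result <- function(x, ...) glance(x$scores, ...)

#' Tidy a synthetic ground truth
#'
#' @param x A `synthetic_truth`.
#' @param ... Unused.
#' @return The planted-driver tibble (`cancer_type`, `gene_id`,
#'   `channel`).
#' @export
tidy.synthetic_truth <- function(x, ...) x$planted
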