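# Evidence integration: the five binary conditions per gene and cancer
# type, the CS-score (their count, 0-5), the PCO-score (CS summed over
# cancer types) with its per-channel decomposition, and a fully
# deterministic ranking.

#' Assemble the five evidence flags per gene and cancer type
#'
#' Joins the five stage tables into one row per gene and cancer type with
#' the binary conditions: `x_scna` (recurrent amplification or deletion),
#' `x_mut` (m-index consensus), `x_fus` (fusion recurrence), `x_de`
#' (differential expression) and `x_surv` (good-or-poor prognosis). A stage
#' that marked a gene unevaluable contributes `FALSE` with its reason;
#' a gene missing entirely from a stage table is an error, since every
#' stage must cover the scoring panel.
#'
#' @param scna Per-cancer tibble(s) from [scna_stage()] /
#'   [flag_recurrent()] / [ingest_external_scna()].
#' @param mutation Per-cancer tibble(s) from [mutation_stage()].
#' @param fusion Per-cancer tibble(s) from [fusion_stage()] /
#'   [fusion_evidence_flag()].
#' @param de Per-cancer tibble(s) from [paired_wilcoxon_de()].
#' @param survival Per-cancer tibble(s) from [survival_stage()].
#' @return A tibble (`gene_id`, `cancer_type`, `x_scna`, `x_mut`, `x_fus`,
#'   `x_de`, `x_surv`, per-flag reason columns).
#' @export
assemble_flags <- function(scna, mutation, fusion, de, survival) {
  scna <- bind_rows(scna)
  mutation <- bind_rows(mutation)
  fusion <- bind_rows(fusion)
  de <- bind_rows(de)
  survival <- bind_rows(survival)
  key <- distinct(scna, .data$gene_id, .data$cancer_type)
  stages <- list(scna = scna, mutation = mutation, fusion = fusion,
                 de = de, survival = survival)
  for (nm in names(stages)) {
    gap <- anti_join(key, stages[[nm]], by = c("gene_id", "cancer_type"))
    if (nrow(gap) > 0) {
      abort(sprintf(
        "stage '%s' does not cover the panel: missing %s",
        nm,
        paste(head(paste(gap$gene_id, gap$cancer_type, sep = "/"), 5),
              collapse = ", ")
      ))
    }
  }
  key |>
    left_join(
      scna |> mutate(
        x_scna = .data$recurrent_amp | .data$recurrent_del,
        reason_scna = sprintf(
          "scna: g_amp=%.3g q_amp=%.3g g_del=%.3g q_del=%.3g",
          .data$g_amp, .data$q_amp, .data$g_del, .data$q_del
        )
      ) |> select("gene_id", "cancer_type", "x_scna", "reason_scna"),
      by = c("gene_id", "cancer_type")
    ) |>
    left_join(
      mutation |> mutate(
        x_mut = .data$significant & .data$coverage == "ok",
        reason_mut = sprintf(
          "mutation: freq=%.3g m_index=%d coverage=%s",
          .data$frequency, .data$m_index, .data$coverage
        )
      ) |> select("gene_id", "cancer_type", "x_mut", "reason_mut"),
      by = c("gene_id", "cancer_type")
    ) |>
    left_join(
      fusion |> mutate(
        x_fus = .data$fusion_flag,
        reason_fus = sprintf("fusion: n_events=%d", .data$n_events)
      ) |> select("gene_id", "cancer_type", "x_fus", "reason_fus"),
      by = c("gene_id", "cancer_type")
    ) |>
    left_join(
      de |> mutate(
        x_de = .data$de_flag,
        reason_de = if_else(
          .data$reason %in% c("no matched normals", "insufficient pairs"),
          paste0("de: ", .data$reason),
          sprintf("de: median_log2fc=%.3g q=%.3g", .data$median_log2fc,
                  .data$q)
        )
      ) |> select("gene_id", "cancer_type", "x_de", "reason_de"),
      by = c("gene_id", "cancer_type")
    ) |>
    left_join(
      survival |> mutate(
        x_surv = .data$prognosis != "none",
        reason_surv = if_else(
          .data$evaluable,
          sprintf("survival: hr=%.3g p=%.3g prognosis=%s", .data$hr,
                  .data$p, .data$prognosis),
          paste0("survival: ", .data$reason)
        )
      ) |> select("gene_id", "cancer_type", "x_surv", "reason_surv"),
      by = c("gene_id", "cancer_type")
    ) |>
    arrange(.data$gene_id, .data$cancer_type)
}

flag_cols <- c("x_scna", "x_mut", "x_fus", "x_de", "x_surv")

#' CS-score: count of satisfied evidence conditions
#'
#' Adds the cancer-specific score, the number of the five binary
#' conditions a gene satisfies in that cancer type (an integer in 0-5).
#'
#' @param flags Tibble from [assemble_flags()].
#' @return `flags` with an integer `cs` column.
#' @export
cs_score <- function(flags) {
  require_columns(flags, flag_cols, "evidence flags")
  m <- as.matrix(flags[, flag_cols])
  storage.mode(m) <- "logical"
  mutate(flags, cs = as.integer(rowSums(m)))
}

#' PCO-score: CS-scores summed over cancer types, with decomposition
#'
#' Sums each gene's CS-scores over all cancer types into the pan-cancer
#' overall score, and decomposes it by evidence channel (the per-channel
#' counts of satisfied conditions across cancer types, which sum exactly
#' to the PCO-score).
#'
#' @param cs Tibble from [cs_score()].
#' @return A list with `pco` (tibble `gene_id`, `pco`, `max_cs`,
#'   `n_cancer_types`) and `components` (long tibble `gene_id`, `channel`,
#'   `count`).
#' @export
pco_score <- function(cs) {
  require_columns(cs, c("gene_id", "cs", flag_cols), "CS table")
  pco <- cs |>
    group_by(.data$gene_id) |>
    summarise(
      pco = sum(.data$cs),
      max_cs = max(.data$cs),
      n_cancer_types = dplyr::n(),
      .groups = "drop"
    )
  components <- cs |>
    tidyr::pivot_longer(dplyr::all_of(flag_cols), names_to = "channel",
                        values_to = "flag") |>
    group_by(.data$gene_id, .data$channel) |>
    summarise(count = sum(.data$flag), .groups = "drop") |>
    mutate(channel = factor(
      sub("^x_", "", .data$channel),
      levels = c("scna", "mut", "fus", "de", "surv")
    )) |>
    arrange(.data$gene_id, .data$channel)
  list(pco = pco, components = components)
}

#' Rank candidate driver genes
#'
#' Orders genes by descending PCO-score; ties are broken by (1) the
#' maximum single-cancer CS-score, (2) the pan-cancer G-score magnitude
#' (the larger of the amplification and deletion sums), then (3) gene id,
#' so the ranking is fully deterministic.
#'
#' @param score_table A `score_table` from [score_candidates()], or the
#'   `pco` tibble from [pco_score()].
#' @param pan_g Optional tibble from [pan_cancer_gscore()] used for the
#'   second tie-break; zero magnitude assumed when absent.
#' @return The pco tibble with a dense `rank` column, ordered.
#' @export
rank_candidates <- function(score_table, pan_g = NULL) {
  pco <- if (inherits(score_table, "score_table")) {
    score_table$pco
  } else {
    as_tibble(score_table)
  }
  if (is.null(pan_g) && inherits(score_table, "score_table")) {
    pan_g <- score_table$pan_g
  }
  mag <- if (!is.null(pan_g)) {
    pan_g |>
      group_by(.data$gene_id) |>
      summarise(pan_g_mag = max(.data$pan_g), .groups = "drop")
  } else {
    tibble(gene_id = pco$gene_id, pan_g_mag = 0)
  }
  pco |>
    left_join(mag, by = "gene_id") |>
    mutate(pan_g_mag = dplyr::coalesce(.data$pan_g_mag, 0)) |>
    arrange(desc(.data$pco), desc(.data$max_cs), desc(.data$pan_g_mag),
            .data$gene_id) |>
    mutate(rank = row_number())
}

#' Score candidates across cancer types
#'
#' Convenience wrapper binding the per-cancer stage outputs into the final
#' score object: evidence flags with reasons, the CS matrix, PCO-scores,
#' channel decomposition and ranking.
#'
#' @inheritParams assemble_flags
#' @param pan_g Optional [pan_cancer_gscore()] tibble for tie-breaking.
#' @return An object of class `score_table`: list with `flags`, `cs`,
#'   `pco` (ranked), `components`, `pan_g`.
#' @export
score_candidates <- function(scna, mutation, fusion, de, survival,
                             pan_g = NULL) {
  flags <- assemble_flags(scna, mutation, fusion, de, survival)
  cs <- cs_score(flags)
  ps <- pco_score(cs)
  if (is.null(pan_g)) {
    scna_all <- bind_rows(scna)
    if (all(c("g_amp", "g_del") %in% names(scna_all))) {
      pan_g <- pan_cancer_gscore(scna_all)
    }
  }
  out <- structure(
    list(flags = flags, cs = cs, pco = ps$pco, components = ps$components,
         pan_g = pan_g),
    class = "score_table"
  )
  out$pco <- rank_candidates(out)
  check_conservation(out)
  out
}

# Conservation invariant: sum of CS == PCO == sum of channel components,
# verified on every assembled score table.
check_conservation <- function(score_table) {
  cs_sum <- score_table$cs |>
    group_by(.data$gene_id) |>
    summarise(s = sum(.data$cs), .groups = "drop")
  comp_sum <- score_table$components |>
    group_by(.data$gene_id) |>
    summarise(s = sum(.data$count), .groups = "drop")
  pco <- arrange(score_table$pco, .data$gene_id)
  stopifnot(
    identical(cs_sum$gene_id, pco$gene_id),
    all(cs_sum$s == pco$pco),
    all(comp_sum$s[match(pco$gene_id, comp_sum$gene_id)] == pco$pco)
  )
  invisible(TRUE)
}

#' @export
print.score_table <- function(x, n = 10, ...) {
  cat(sprintf(
    "<score_table> %d gene(s) x %d cancer type(s)\nTop candidates:\n",
    dplyr::n_distinct(x$cs$gene_id), dplyr::n_distinct(x$cs$cancer_type)
  ))
  print(head(x$pco, n))
  invisible(x)
}
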