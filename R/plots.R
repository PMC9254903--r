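# ggplot2 visualisations of the score and stage results.

channel_labels <- c(
  scna = "SCNA", mut = "Mutation", fus = "Fusion", de = "Expression",
  surv = "Survival"
)

#' Stacked PCO-score decomposition
#'
#' Horizontal stacked bars of the top genes' PCO-scores, split by evidence
#' channel (copy number, mutation, fusion, expression, survival).
#'
#' @param object A `score_table`.
#' @param top_n Number of top-ranked genes to show (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.score_table <- function(object, top_n = 20, ...) {
  top <- head(object$pco, top_n)
  df <- object$components |>
    filter(.data$gene_id %in% top$gene_id, .data$count > 0) |>
    mutate(
      gene_id = factor(.data$gene_id, levels = rev(top$gene_id)),
      channel = factor(channel_labels[as.character(.data$channel)],
                       levels = unname(channel_labels))
    )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$count, y = .data$gene_id, fill = .data$channel
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "PCO-score (per-channel contribution)", y = NULL,
                  fill = "Evidence") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.score_table
#' @param object A `pipeline_result`.
#' @export
autoplot.pipeline_result <- function(object, top_n = 20, ...) {
  autoplot(object$scores, top_n = top_n, ...)
}

#' CS-score heat map
#'
#' Genes by cancer types, tile fill = CS-score.
#'
#' @param score_table A `score_table`.
#' @param top_n Number of top-ranked genes to show (default 20).
#' @return A ggplot object.
#' @export
plot_cs_heatmap <- function(score_table, top_n = 20) {
  top <- head(score_table$pco, top_n)
  df <- score_table$cs |>
    filter(.data$gene_id %in% top$gene_id) |>
    mutate(gene_id = factor(.data$gene_id, levels = rev(top$gene_id)))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$cancer_type, y = .data$gene_id, fill = .data$cs
  )) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_gradient(low = "grey95", high = "firebrick",
                                 limits = c(0, 5)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "CS-score") +
    ggplot2::theme_minimal()
}

#' Volcano plot of the paired differential-expression results
#'
#' Median log2 fold-change against -log10 q, coloured by flag status.
#'
#' @param de A [paired_wilcoxon_de()] tibble (one or several cancer
#'   types).
#' @return A ggplot object.
#' @export
plot_de_volcano <- function(de) {
  df <- filter(de, !is.na(.data$p))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$median_log2fc, y = -log10(pmax(.data$q, 1e-300)),
    colour = .data$de_flag
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "purple3")) +
    ggplot2::labs(x = "median log2 fold-change (tumour vs normal)",
                  y = "-log10 q", colour = "DE") +
    ggplot2::theme_minimal()
}

#' Hazard-ratio bubble plot of the survival stage
#'
#' Genes by cancer types; point size encodes -log10 p, colour the
#' prognosis call.
#'
#' @param survival A [survival_stage()] tibble (one or several cancer
#'   types).
#' @return A ggplot object.
#' @export
plot_survival_bubbles <- function(survival) {
  df <- filter(survival, .data$evaluable)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$cancer_type, y = .data$gene_id,
    size = -log10(pmax(.data$p, 1e-300)), colour = .data$prognosis
  )) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(
      poor = "purple3", good = "steelblue", none = "grey70"
    )) +
    ggplot2::labs(x = NULL, y = NULL, size = "-log10 p",
                  colour = "Prognosis") +
    ggplot2::theme_minimal()
}
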