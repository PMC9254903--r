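# Expression evidence: broad-expression filtering, paired tumour/normal
# differential expression by the Wilcoxon signed-rank test, and the
# expression / copy-number Pearson correlation.

#' Broad-expression filter
#'
#' A gene passes when the fraction of tumour specimens with FPKM at or
#' above `fpkm_min` is at least `fraction` (both bounds inclusive;
#' defaults FPKM >= 1 in at least 90% of tumour specimens).
#'
#' @param expression Expression list (`values`, `sample_meta`) as returned
#'   by [read_expression_matrix()] or found in a `cohort_bundle`.
#' @param fpkm_min,fraction Filter parameters.
#' @return A tibble (`gene_id`, `frac_expressed`, `broad_expressed`).
#' @export
broad_expression_filter <- function(expression, fpkm_min = 1,
                                    fraction = 0.9) {
  meta <- expression$sample_meta
  tum <- meta$sample_id[meta$tissue == "tumour"]
  if (length(tum) == 0) abort("broad_expression_filter: no tumour specimens")
  m <- as.matrix(expression$values[, tum, drop = FALSE])
  frac <- rowMeans(m >= fpkm_min)
  tibble(
    gene_id = expression$values$gene_id,
    frac_expressed = frac,
    broad_expressed = frac >= fraction
  )
}

# Exact (and tie-corrected approximate) one-sample Wilcoxon signed-rank
# test on a vector of paired differences. Zero differences are dropped
# (the classical zero-drop convention). For effective n <= exact_limit the
# two-sided p comes from the exact null distribution of the signed-rank
# statistic, computed by dynamic programming over doubled midranks (exact
# also under tied absolute differences, where the classical distribution
# tables do not apply); otherwise a normal approximation with tie
# correction and continuity correction is used, matching
# stats::wilcox.test(correct = TRUE).
signed_rank_test <- function(d, exact_limit = 25L) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = NA_real_, p = 1, n_eff = 0L, exact = NA))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_limit) {
    # exact null: V = sum r_i B_i, B_i iid Bernoulli(1/2); DP over 2*r
    r2 <- as.integer(round(2 * r))
    probs <- 1
    for (ri in r2) {
      padded <- c(probs, rep(0, ri))
      probs <- (padded + c(rep(0, ri), probs)) / 2
    }
    v2 <- as.integer(round(2 * v))
    p_le <- sum(probs[seq_len(v2 + 1L)])
    p_ge <- sum(probs[(v2 + 1L):length(probs)])
    p <- min(1, 2 * min(p_le, p_ge))
    list(statistic = v, p = p, n_eff = n, exact = TRUE)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- v - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2) # continuity correction
    list(statistic = v, p = min(1, 2 * pnorm(-abs(z))), n_eff = n,
         exact = FALSE)
  }
}

#' Paired tumour/normal differential expression (Wilcoxon signed-rank)
#'
#' For each gene, computes per-patient differences
#' `d_i = log2(FPKM_tumour + 1) - log2(FPKM_normal + 1)` over matched
#' tumour/normal pairs and tests them with the signed-rank test (exact for
#' effective n <= 25 after dropping zero differences, tie-corrected normal
#' approximation otherwise). q-values are Benjamini-Hochberg across the
#' panel within the cancer type. A gene is flagged differentially expressed
#' when `q < de_q` and `|median_log2fc| >= log2(fc_min)`; its direction
#' (up/down in tumour) follows the sign of the median log2 fold-change.
#' Cohorts with fewer than `min_pairs` matched pairs report every gene
#' unflagged with the reason recorded.
#'
#' @param expression Expression list (`values`, `sample_meta`).
#' @param min_pairs Minimum number of matched pairs (default 10).
#' @param de_q BH q-value threshold (default 0.05).
#' @param fc_min Fold-change floor on the linear scale (default 1.5).
#' @param cancer_type Optional label stamped onto the result.
#' @return A tibble (`gene_id`, `cancer_type`, `n_pairs`, `median_log2fc`,
#'   `p`, `q`, `direction`, `de_flag`, `reason`).
#' @export
paired_wilcoxon_de <- function(expression, min_pairs = 10L, de_q = 0.05,
                               fc_min = 1.5, cancer_type = NA_character_) {
  values <- expression$values
  meta <- expression$sample_meta
  pairs <- meta |>
    filter(.data$tissue %in% c("tumour", "normal")) |>
    tidyr::pivot_wider(
      id_cols = "patient_id", names_from = "tissue",
      values_from = "sample_id"
    )
  have_both <- c("tumour", "normal") %in% names(pairs)
  if (!all(have_both)) {
    pairs <- pairs[0, ]
  } else {
    pairs <- filter(pairs, !is.na(.data$tumour), !is.na(.data$normal))
  }
  genes <- values$gene_id
  n_pairs <- nrow(pairs)
  if (n_pairs < min_pairs) {
    reason <- if (n_pairs == 0) "no matched normals" else "insufficient pairs"
    return(tibble(
      gene_id = genes, cancer_type = cancer_type, n_pairs = n_pairs,
      median_log2fc = NA_real_, p = NA_real_, q = NA_real_,
      direction = "none", de_flag = FALSE, reason = reason
    ))
  }
  tum <- log2(as.matrix(values[, pairs$tumour, drop = FALSE]) + 1)
  nor <- log2(as.matrix(values[, pairs$normal, drop = FALSE]) + 1)
  diffs <- tum - nor
  tests <- purrr::map(seq_along(genes), ~ signed_rank_test(diffs[.x, ]))
  out <- tibble(
    gene_id = genes,
    cancer_type = cancer_type,
    n_pairs = n_pairs,
    median_log2fc = apply(diffs, 1, median),
    p = purrr::map_dbl(tests, "p")
  )
  out$q <- bh_adjust(out$p)
  out$de_flag <- out$q < de_q & abs(out$median_log2fc) >= log2(fc_min)
  out$direction <- if_else(
    out$de_flag, if_else(out$median_log2fc > 0, "up", "down"), "none"
  )
  out$reason <- if_else(out$de_flag, "de", "not significant")
  select(out, "gene_id", "cancer_type", "n_pairs", "median_log2fc", "p",
         "q", "direction", "de_flag", "reason")
}

#' Expression / copy-number Pearson correlation
#'
#' For each broadly expressed gene, the Pearson correlation between the
#' gene-level copy-number log2 ratio and `log2(FPKM + 1)` over the tumour
#' samples shared by both matrices, with a two-sided test. A gene is
#' flagged correlated when the correlation is positive and `p < p_corr`
#' (default 0.001). Genes failing the broad-expression filter, with fewer
#' than 3 shared samples, or with zero variance in either vector are
#' reported uncorrelated with the reason recorded.
#'
#' @param expression Expression list (`values`, `sample_meta`).
#' @param gene_cn Long gene-CN tibble from [segments_to_gene_matrix()].
#' @param p_corr Significance cut-off (default 0.001).
#' @param fpkm_min,fraction Broad-expression filter parameters.
#' @param cancer_type Optional label stamped onto the result.
#' @return A tibble (`gene_id`, `cancer_type`, `n`, `r`, `p`, `correlated`,
#'   `reason`).
#' @export
expr_cnv_correlation <- function(expression, gene_cn, p_corr = 0.001,
                                 fpkm_min = 1, fraction = 0.9,
                                 cancer_type = NA_character_) {
  broad <- broad_expression_filter(expression, fpkm_min, fraction)
  meta <- expression$sample_meta
  tum <- meta$sample_id[meta$tissue == "tumour"]
  cn <- as_cn_matrix(gene_cn)
  shared <- intersect(tum, colnames(cn))
  expr_m <- log2(as.matrix(
    expression$values[, intersect(shared, names(expression$values)),
                      drop = FALSE]
  ) + 1)
  rownames(expr_m) <- expression$values$gene_id
  shared <- intersect(shared, colnames(expr_m))
  rows <- purrr::map(expression$values$gene_id, function(g) {
    if (!broad$broad_expressed[match(g, broad$gene_id)]) {
      return(tibble(gene_id = g, n = length(shared), r = NA_real_,
                    p = NA_real_, correlated = FALSE,
                    reason = "not broadly expressed"))
    }
    if (!(g %in% rownames(cn)) || length(shared) < 3) {
      return(tibble(gene_id = g, n = length(shared), r = NA_real_,
                    p = NA_real_, correlated = FALSE,
                    reason = "insufficient shared samples"))
    }
    x <- cn[g, shared]
    y <- expr_m[g, shared]
    if (sd(x) == 0 || sd(y) == 0) {
      return(tibble(gene_id = g, n = length(shared), r = NA_real_,
                    p = NA_real_, correlated = FALSE,
                    reason = "zero variance"))
    }
    ct <- stats::cor.test(x, y, method = "pearson",
                          alternative = "two.sided")
    tibble(
      gene_id = g, n = length(shared), r = unname(ct$estimate),
      p = ct$p.value, correlated = ct$p.value < p_corr & ct$estimate > 0,
      reason = "tested"
    )
  })
  bind_rows(rows) |> mutate(cancer_type = cancer_type) |>
    select("gene_id", "cancer_type", "n", "r", "p", "correlated", "reason")
}

#' Run the full expression stage on one cohort bundle
#'
#' Broad-expression filter, paired differential expression, and (when a
#' gene-CN matrix is supplied) the copy-number correlation.
#'
#' @param bundle A `cohort_bundle`.
#' @param min_pairs,de_q,fc_min,p_corr Stage parameters.
#' @param gene_cn Optional gene-CN tibble (e.g. the `gene_cn` attribute of
#'   [scna_stage()] output); when `NULL` the correlation is skipped.
#' @return A list with `de` (the [paired_wilcoxon_de()] table), `broad`
#'   and optionally `correlation`.
#' @export
expression_stage <- function(bundle, min_pairs = 10L, de_q = 0.05,
                             fc_min = 1.5, p_corr = 0.001, gene_cn = NULL) {
  de <- paired_wilcoxon_de(
    bundle$expression, min_pairs = min_pairs, de_q = de_q, fc_min = fc_min,
    cancer_type = bundle$cancer_type
  )
  broad <- broad_expression_filter(bundle$expression)
  corr <- if (!is.null(gene_cn)) {
    expr_cnv_correlation(bundle$expression, gene_cn, p_corr = p_corr,
                         cancer_type = bundle$cancer_type)
  }
  list(de = de, broad = broad, correlation = corr)
}
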