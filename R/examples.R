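# Worked example: CHD7 in colorectal cancer.

#' Worked example: scoring CHD7 in colorectal cancer
#'
#' Encodes the published colorectal-cancer alteration profile of CHD7 as
#' stage inputs and pushes them through the five evidence stages and the
#' CS-score formula: amplification in 331 of 617 tumours (53.7%) at focal
#' amplitude, somatic mutations in 8% of tumours, four CHD7-TOX fusion
#' events, tumour overexpression against matched normals, and no
#' overall-survival association (encoded as a sign-balanced null design in
#' which the partial-likelihood score vanishes identically, so the fitted
#' log hazard ratio is exactly zero). With the standard thresholds
#' (q <= 0.25 and G >= 0.1; m-index >= 2; fusion recurrence >= 2; BH
#' q < 0.05 with 1.5-fold floor; prognosis at p < 0.1) CHD7 satisfies four
#' of the five conditions, the maximum single-cancer CS-score in the
#' pan-cancer screen.
#'
#' @param seed Integer seed for the background noise of the encoded
#'   cohort (the conclusion does not depend on it).
#' @param n_decoys Decoy genes added to the panel so the permutation null
#'   and BH corrections operate over a non-trivial panel (default 100).
#' @return A list: `cs` (the CHD7 CS-score), `flags` (the scored flag
#'   row), `cs_table` (all genes), and the five stage tables.
#' @export
#' @examples
#' crc_chd7_example(seed = 1)$cs
crc_chd7_example <- function(seed = 1L, n_decoys = 100L) {
  cancer <- "COADREAD"
  n_tumour <- 617L
  n_amp <- 331L     # 53.7% of 617
  n_mut <- 49L      # 8% of 617
  n_pairs <- 32L
  panel <- bind_rows(atpcr_panel(), decoy_genes(n_decoys, atpcr_panel()))
  genes <- panel$gene_id
  tumours <- sprintf("%s-%04d-T", cancer, seq_len(n_tumour))

  # --- SCNA: 331/617 tumours carry a focal CHD7 amplification ----------
  gene_cn <- withr::with_seed(child_seed(seed, "crc-cn"), {
    cn <- matrix(rnorm(length(genes) * n_tumour, 0, 0.05),
                 nrow = length(genes), dimnames = list(genes, tumours))
    cn["CHD7", seq_len(n_amp)] <- cn["CHD7", seq_len(n_amp)] + 0.5
    tibble(
      gene_id = rep(genes, times = n_tumour),
      sample_id = rep(tumours, each = length(genes)),
      log2_ratio = as.vector(cn)
    )
  })
  scna <- gscore_qvalues(gene_cn, n_perm = 200,
                         seed = child_seed(seed, "crc-perm")) |>
    flag_recurrent(cancer_type = cancer)

  # --- Mutation: 8% frequency, noise-free pseudo-caller consensus ------
  mutations <- tibble(
    sample_id = tumours[seq_len(n_mut)],
    gene_id = "CHD7",
    variant_class = "missense"
  )
  freqs <- mutation_frequency(mutations, tumours, panel = panel)
  calls <- pseudo_callers(freqs, background_rate = 0.01, epsilon = 0,
                          seed = child_seed(seed, "crc-callers"))
  mutation <- freqs |>
    left_join(m_index(calls), by = "gene_id") |>
    mutate(cancer_type = cancer)

  # --- Fusion: four CHD7-TOX events ------------------------------------
  fusions <- tibble(
    sample_id = tumours[seq_len(4)],
    cancer_type = cancer,
    gene_5p = "CHD7",
    gene_3p = "TOX"
  )
  fusion <- count_fusions(fusions, panel = panel) |>
    fusion_evidence_flag(cancer, mode = "within_cancer")

  # --- Expression: CHD7 overexpressed in tumour/normal pairs -----------
  expression <- withr::with_seed(child_seed(seed, "crc-expr"), {
    pts <- sprintf("%s-%04d", cancer, seq_len(n_pairs))
    base <- rnorm(length(genes), 4, 1)
    noise <- function() matrix(rnorm(length(genes) * n_pairs, 0, 0.3),
                               nrow = length(genes))
    tum_log2 <- base + noise()
    tum_log2[genes == "CHD7", ] <- tum_log2[genes == "CHD7", ] + 1.2
    nor_log2 <- base + noise()
    vals <- bind_cols(
      tibble(gene_id = genes),
      as_tibble(setNames(as.data.frame(2^tum_log2), paste0(pts, "-T"))),
      as_tibble(setNames(as.data.frame(2^nor_log2), paste0(pts, "-N")))
    )
    meta <- tibble(
      sample_id = c(paste0(pts, "-T"), paste0(pts, "-N")),
      patient_id = rep(pts, 2),
      tissue = rep(c("tumour", "normal"), each = n_pairs)
    )
    list(values = vals, sample_meta = meta)
  })
  de <- paired_wilcoxon_de(expression, cancer_type = cancer)

  # --- Survival: no OS association, by exact sign balance --------------
  # Pairs of samples share event time and status but carry opposite
  # standardized log-expression, so the Cox partial-likelihood score is
  # identically zero and the fitted log HR is exactly 0 (p = 1).
  half <- n_tumour %/% 2
  z <- seq(-1.5, 1.5, length.out = half)
  fpkm <- 2^(5 + c(z, -z)) - 1
  names(fpkm) <- tumours[seq_len(2 * half)]
  clinical <- tibble(
    sample_id = tumours[seq_len(2 * half)],
    os_time = rep(30 * seq_len(half), 2),
    os_event = rep(1L, 2 * half)
  )
  surv_fit <- fit_univariate_ph(fpkm, clinical)
  survival <- tibble(gene_id = genes) |>
    bind_cols(surv_fit[rep(1, length(genes)), ]) |>
    mutate(
      cancer_type = cancer,
      prognosis = classify_prognosis(.data$hr, .data$p)
    )

  flags <- assemble_flags(scna, mutation, fusion, de, survival)
  cs_table <- cs_score(flags)
  chd7 <- filter(cs_table, .data$gene_id == "CHD7")
  list(
    cs = chd7$cs,
    flags = chd7,
    cs_table = cs_table,
    scna = scna, mutation = mutation, fusion = fusion, de = de,
    survival = survival,
    n_tumour = n_tumour
  )
}
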