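# Configuration-driven orchestration of all stages over multi-cancer
# inputs, with provenance and a deterministic output layout.

default_run_config <- function() {
  list(
    cohorts = list(),          # named list: cancer_type -> directory
    gene_panel = NULL,         # optional BED path overriding cohort BEDs
    scna_mode = "lite",        # "lite" or "ingest"
    external_scna = NULL,      # TSV path for ingest mode
    q_max = 0.25,
    g_min = 0.1,
    amp_threshold = 0.1,
    m_min = 2L,
    background_rate = 0.01,
    r_min = 2L,
    fusion_mode = "within_cancer",
    fusion_ordered = TRUE,
    min_pairs = 10L,
    de_q = 0.05,
    fc_min = 1.5,
    p_corr = 0.001,
    surv_p = 0.1,
    covariate = "continuous",
    n_perm = 500L,
    seed = 1L,
    out_dir = "omicdriver_out",
    top_n = 10L
  )
}

config_ranges <- function() {
  list(
    q_max = c(0, 1), g_min = c(0, Inf), amp_threshold = c(1e-12, Inf),
    m_min = c(1, 5), background_rate = c(1e-12, 1), r_min = c(1, Inf),
    min_pairs = c(1, Inf), de_q = c(0, 1), fc_min = c(1, Inf),
    p_corr = c(0, 1), surv_p = c(0, 1), n_perm = c(100, Inf),
    top_n = c(1, Inf)
  )
}

#' Validate and normalize a run configuration
#'
#' Accepts a YAML/JSON file path or a named list; fills every default,
#' rejects unknown keys (no silent typos) and out-of-range thresholds, and
#' records every deviation from the default thresholds so the run summary
#' can flag them.
#'
#' @param config Path to a YAML or JSON file, or a named list.
#' @return A normalized config list of class `run_config` with attribute
#'   `deviations` (character vector of non-default threshold settings).
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
    if (is.null(config)) config <- list()
  }
  defaults <- default_run_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defaults, config)
  ranges <- config_ranges()
  errors <- character()
  for (k in names(ranges)) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) ||
        v < ranges[[k]][1] || v > ranges[[k]][2]) {
      errors <- c(errors, sprintf(
        "%s = %s outside [%g, %g]", k, format(v), ranges[[k]][1],
        ranges[[k]][2]
      ))
    }
  }
  if (!cfg$fusion_mode %in% c("within_cancer", "pan_cancer_pair")) {
    errors <- c(errors, "fusion_mode must be within_cancer|pan_cancer_pair")
  }
  if (!cfg$scna_mode %in% c("lite", "ingest")) {
    errors <- c(errors, "scna_mode must be lite|ingest")
  }
  if (cfg$scna_mode == "ingest" && is.null(cfg$external_scna)) {
    errors <- c(errors, "scna_mode 'ingest' needs external_scna")
  }
  if (!cfg$covariate %in% c("continuous", "median")) {
    errors <- c(errors, "covariate must be continuous|median")
  }
  if (length(errors) > 0) {
    abort(paste0("invalid configuration:\n  ",
                 paste(errors, collapse = "\n  ")))
  }
  tunable <- names(ranges)
  deviations <- tunable[vapply(
    tunable, function(k) !isTRUE(all.equal(cfg[[k]], defaults[[k]])),
    logical(1)
  )]
  structure(cfg, class = "run_config",
            deviations = sprintf("%s = %s", deviations,
                                 vapply(cfg[deviations], format,
                                        character(1))))
}

#' Run all scoring stages over a set of cohort bundles
#'
#' In-memory core of the pipeline: runs the SCNA, mutation, fusion,
#' expression and survival stages per cancer type (fusion pair recurrence
#' is assessed pan-cancer over the pooled events), assembles the evidence
#' flags and returns the ranked `score_table` together with every stage
#' table.
#'
#' @param bundles Named list of `cohort_bundle` objects.
#' @param config A `run_config` (or list passed to [validate_config()]).
#' @return A list of class `pipeline_result`: `scores` (`score_table`),
#'   per-stage tibbles, `pan_g`, and the effective `config`.
#' @export
run_cohorts <- function(bundles, config = list()) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  if (inherits(bundles, "cohort_bundle")) bundles <- list(bundles)
  nm <- vapply(bundles, function(b) b$cancer_type, character(1))
  names(bundles) <- nm

  scna <- if (config$scna_mode == "ingest") {
    ingested <- ingest_external_scna(config$external_scna,
                                     q_max = config$q_max,
                                     g_min = config$g_min)
    purrr::map(bundles, function(b) {
      filter(ingested, .data$cancer_type == b$cancer_type)
    })
  } else {
    purrr::map(bundles, function(b) {
      scna_stage(b, q_max = config$q_max, g_min = config$g_min,
                 amplitude_threshold = config$amp_threshold,
                 n_perm = config$n_perm, seed = config$seed)
    })
  }
  mutation <- purrr::map(bundles, function(b) {
    mutation_stage(b, m_min = config$m_min,
                   background_rate = config$background_rate,
                   seed = config$seed)
  })
  # fusion recurrence is defined over all cancer specimens: pool events
  pooled_fusions <- bind_rows(purrr::map(bundles, function(b) {
    fus <- b$fusions
    if (!"cancer_type" %in% names(fus) || all(is.na(fus$cancer_type))) {
      fus$cancer_type <- b$cancer_type
    }
    fus
  }))
  panel_genes <- bundles[[1]]$gene_model
  fusion_summary <- count_fusions(pooled_fusions, panel = panel_genes,
                                  r_min = config$r_min,
                                  ordered = config$fusion_ordered)
  fusion <- purrr::map(bundles, function(b) {
    fusion_evidence_flag(fusion_summary, b$cancer_type,
                         mode = config$fusion_mode)
  })
  expression <- purrr::map(bundles, function(b) {
    gene_cn <- attr(scna[[b$cancer_type]], "gene_cn")
    expression_stage(b, min_pairs = config$min_pairs, de_q = config$de_q,
                     fc_min = config$fc_min, p_corr = config$p_corr,
                     gene_cn = gene_cn)
  })
  surv <- purrr::map(bundles, function(b) {
    survival_stage(b, p_threshold = config$surv_p,
                   covariate = config$covariate)
  })
  de <- purrr::map(expression, "de")
  scores <- score_candidates(scna, mutation, fusion, de, surv)
  structure(
    list(
      scores = scores,
      scna = bind_rows(scna),
      mutation = bind_rows(mutation),
      fusion = bind_rows(fusion),
      fusion_pairs = fusion_summary$pair_events,
      de = bind_rows(de),
      correlation = bind_rows(purrr::compact(
        purrr::map(expression, "correlation")
      )),
      survival = bind_rows(surv),
      pan_g = scores$pan_g,
      config = config
    ),
    class = "pipeline_result"
  )
}

#' Run the full pipeline from a configuration
#'
#' File-based entry point: reads every configured cohort directory,
#' executes the stages in dependency order, writes all stage tables, the
#' score tables and a machine-readable run summary into `out_dir`, and
#' returns the in-memory result. Re-running with an identical
#' configuration and seed produces byte-identical outputs.
#'
#' @param config Path to a YAML/JSON config, or a named list. The
#'   `cohorts` entry maps cancer-type labels to cohort directories (as
#'   written by [write_cohort_dir()]).
#' @return The `pipeline_result`, invisibly.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  if (length(config$cohorts) == 0) {
    abort("config declares no cohorts")
  }
  missing_dir <- names(config$cohorts)[!vapply(
    unlist(config$cohorts), dir.exists, logical(1)
  )]
  if (length(missing_dir) > 0) {
    abort(sprintf("missing input directory for cancer type(s): %s",
                  paste(missing_dir, collapse = ", ")))
  }
  bundles <- purrr::imap(config$cohorts, function(dir, ct) {
    read_cohort_dir(dir, cancer_type = ct)
  })
  result <- run_cohorts(bundles, config)
  attr(result, "input_hashes") <- purrr::map(config$cohorts, function(d) {
    files <- sort(list.files(d, full.names = TRUE))
    as.list(setNames(unname(tools::md5sum(files)), basename(files)))
  })
  write_pipeline_output(result, config$out_dir)
  invisible(result)
}

#' Write every pipeline output table plus the run summary
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_output <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scores <- result$scores
  write_stage_table(result$scna, file.path(out_dir, "scna_results.tsv"))
  write_stage_table(result$pan_g,
                    file.path(out_dir, "pan_cancer_gscore.tsv"))
  write_stage_table(result$mutation,
                    file.path(out_dir, "mutation_results.tsv"))
  write_stage_table(result$fusion,
                    file.path(out_dir, "fusion_results.tsv"))
  write_stage_table(result$fusion_pairs,
                    file.path(out_dir, "fusion_pairs.tsv"))
  write_stage_table(result$de, file.path(out_dir, "de_results.tsv"))
  if (nrow(result$correlation) > 0) {
    write_stage_table(result$correlation,
                      file.path(out_dir, "expr_cnv_correlation.tsv"))
  }
  write_stage_table(result$survival,
                    file.path(out_dir, "survival_results.tsv"))
  write_stage_table(scores$flags,
                    file.path(out_dir, "evidence_flags.tsv"))
  write_stage_table(scores$cs, file.path(out_dir, "cs_scores.tsv"))
  write_stage_table(scores$pco, file.path(out_dir, "pco_scores.tsv"))
  cfg <- result$config
  top <- head(scores$pco, cfg$top_n)
  write_run_summary(
    list(
      package = "omicdriver",
      version = as.character(utils::packageVersion("omicdriver")),
      seed = cfg$seed,
      thresholds = cfg[names(config_ranges())],
      scna_mode = cfg$scna_mode,
      fusion_mode = cfg$fusion_mode,
      covariate = cfg$covariate,
      deviations_from_defaults = as.list(attr(cfg, "deviations")),
      n_genes = dplyr::n_distinct(scores$cs$gene_id),
      cancer_types = sort(unique(scores$cs$cancer_type)),
      rows = list(
        scna = nrow(result$scna), mutation = nrow(result$mutation),
        fusion = nrow(result$fusion), de = nrow(result$de),
        survival = nrow(result$survival)
      ),
      top_candidates = purrr::map(seq_len(nrow(top)), function(i) {
        list(gene_id = top$gene_id[i], pco = top$pco[i],
             rank = top$rank[i])
      }),
      input_hashes = attr(result, "input_hashes")
    ),
    file.path(out_dir, "run_summary.json")
  )
  invisible(out_dir)
}
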