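# Deterministic stage-table output.

#' Write a stage result table as deterministic TSV
#'
#' All stage outputs go through this writer: tab-delimited, fixed column
#' order (as given), floating values rendered at 6 significant digits, and a
#' deterministic row order (gene, then cancer type, then any remaining
#' columns, lexicographically). Re-running on identical input produces a
#' byte-identical file.
#'
#' @param result_table A tibble (any stage result).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stage_table <- function(result_table, path) {
  df <- as_tibble(result_table)
  sort_cols <- intersect(
    c("gene_id", "cancer_type", "direction", "sample_id", "chrom", "start"),
    names(df)
  )
  if (length(sort_cols) > 0) {
    df <- arrange(df, dplyr::pick(dplyr::all_of(sort_cols)))
  }
  out <- mutate(df, across(dplyr::everything(), format_sig6))
  con <- tryCatch(
    file(path, open = "wb"),
    error = function(e) abort(sprintf("cannot write '%s': %s", path, conditionMessage(e)))
  )
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out) > 0) {
    lines <- do.call(paste, c(unname(as.list(out)), sep = "\t"))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write a machine-readable run summary
#'
#' @param summary A named list (thresholds, seeds, row counts, warnings...).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
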