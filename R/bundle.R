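# The per-cancer multi-omic data bundle.

#' Assemble and validate one cancer type's multi-omic bundle
#'
#' Collects the aligned tables of one cancer type and validates the
#' cross-table invariants: every sample referenced by any omic table appears
#' in the sample registry, tumour/normal expression pairing is consistent,
#' and the gene panel is valid.
#'
#' @param cancer_type Cancer-type label.
#' @param gene_model Gene panel tibble (see [validate_gene_model()]).
#' @param segments Segment tibble from [read_seg()] or the simulator.
#' @param mutations Mutation tibble from [read_maf_lite()].
#' @param fusions Fusion tibble from [read_fusion_table()].
#' @param expression List with `values` and `sample_meta`
#'   (see [read_expression_matrix()]).
#' @param clinical Clinical tibble from [read_clinical()].
#' @param driver_calls Optional gene-by-algorithm logical tibble.
#' @param sample_registry Optional tibble (`sample_id`, `tissue`); derived
#'   from the other tables when omitted.
#' @return An object of class `cohort_bundle`.
#' @export
cohort_bundle <- function(cancer_type, gene_model, segments, mutations,
                          fusions, expression, clinical,
                          driver_calls = NULL, sample_registry = NULL) {
  gene_model <- validate_gene_model(gene_model)
  validate_expression(expression$values, expression$sample_meta)
  if (is.null(sample_registry)) {
    sample_registry <- dplyr::bind_rows(
      select(expression$sample_meta, "sample_id", "tissue"),
      tibble(sample_id = unique(segments$sample_id), tissue = "tumour"),
      tibble(sample_id = unique(mutations$sample_id), tissue = "tumour"),
      tibble(sample_id = unique(fusions$sample_id), tissue = "tumour"),
      tibble(sample_id = unique(clinical$sample_id), tissue = "tumour")
    ) |> distinct(.data$sample_id, .keep_all = TRUE)
  }
  for (tab in list(segments = segments, mutations = mutations,
                   fusions = fusions, clinical = clinical)) {
    unknown <- setdiff(tab$sample_id, sample_registry$sample_id)
    if (length(unknown) > 0) {
      abort(sprintf(
        "bundle '%s': sample(s) absent from registry: %s",
        cancer_type, paste(head(unknown, 5), collapse = ", ")
      ))
    }
  }
  structure(
    list(
      cancer_type = cancer_type,
      gene_model = gene_model,
      segments = as_tibble(segments),
      mutations = as_tibble(mutations),
      driver_calls = driver_calls,
      fusions = as_tibble(fusions),
      expression = expression,
      clinical = as_tibble(clinical),
      sample_registry = as_tibble(sample_registry)
    ),
    class = "cohort_bundle"
  )
}

#' @export
print.cohort_bundle <- function(x, ...) {
  n_t <- sum(x$expression$sample_meta$tissue == "tumour")
  n_n <- sum(x$expression$sample_meta$tissue == "normal")
  cat(sprintf(
    paste0(
      "<cohort_bundle> %s\n  genes: %d  tumours: %d  normals: %d\n",
      "  segments: %d  mutations: %d  fusions: %d  clinical: %d\n"
    ),
    x$cancer_type, nrow(x$gene_model), n_t, n_n,
    nrow(x$segments), nrow(x$mutations), nrow(x$fusions), nrow(x$clinical)
  ))
  invisible(x)
}

# Tumour sample ids of a bundle, in registry order.
tumour_samples <- function(bundle) {
  meta <- bundle$expression$sample_meta
  meta$sample_id[meta$tissue == "tumour"]
}

#' Write a cohort bundle to a directory of standard-format files
#'
#' Emits SEG, MAF-lite, fusion TSV, expression TSV + sample metadata,
#' clinical TSV, BED6 gene model and (if present) the driver-call matrix.
#'
#' @param bundle A `cohort_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_dir <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seg <- bundle$segments |>
    rename(sample = "sample_id", loc.start = "start", loc.end = "end",
           num.mark = "n_markers", seg.mean = "log2_ratio")
  write_stage_table(seg, file.path(dir, "segments.seg"))
  maf <- bundle$mutations |>
    rename(Tumor_Sample_Barcode = "sample_id", Hugo_Symbol = "gene_id",
           Variant_Classification = "variant_class") |>
    mutate(Variant_Classification = unmap_variant_class(.data$Variant_Classification))
  write_stage_table(maf, file.path(dir, "mutations.maf"))
  write_stage_table(
    rename(bundle$fusions, sample = "sample_id", gene5 = "gene_5p",
           gene3 = "gene_3p"),
    file.path(dir, "fusions.tsv")
  )
  write_stage_table(bundle$expression$values, file.path(dir, "expression.tsv"))
  write_stage_table(bundle$expression$sample_meta,
                    file.path(dir, "sample_meta.tsv"))
  write_stage_table(
    rename(bundle$clinical, sample = "sample_id", OS.time = "os_time",
           OS.event = "os_event"),
    file.path(dir, "clinical.tsv")
  )
  write_gene_bed(bundle$gene_model, file.path(dir, "genes.bed"))
  if (!is.null(bundle$driver_calls)) {
    write_stage_table(bundle$driver_calls, file.path(dir, "driver_calls.tsv"))
  }
  invisible(dir)
}

# Inverse of the read-time class mapping, for round-tripping simulated MAFs.
unmap_variant_class <- function(x) {
  back <- c(
    missense = "Missense_Mutation",
    nonsense = "Nonsense_Mutation",
    frameshift_indel = "Frame_Shift_Del",
    inframe_indel = "In_Frame_Del",
    splice = "Splice_Site",
    other = "Translation_Start_Site"
  )
  unname(back[x])
}

#' Read a cohort bundle from a directory written by [write_cohort_dir()]
#'
#' @param dir Directory path.
#' @param cancer_type Cancer-type label (defaults to the directory name).
#' @return A `cohort_bundle`.
#' @export
read_cohort_dir <- function(dir, cancer_type = basename(dir)) {
  expr <- read_expression_matrix(
    file.path(dir, "expression.tsv"), file.path(dir, "sample_meta.tsv")
  )
  calls_path <- file.path(dir, "driver_calls.tsv")
  cohort_bundle(
    cancer_type = cancer_type,
    gene_model = read_gene_bed(file.path(dir, "genes.bed")),
    segments = read_seg(file.path(dir, "segments.seg")),
    mutations = read_maf_lite(file.path(dir, "mutations.maf")),
    fusions = read_fusion_table(file.path(dir, "fusions.tsv")),
    expression = expr,
    clinical = read_clinical(file.path(dir, "clinical.tsv")),
    driver_calls = if (file.exists(calls_path)) read_driver_calls(calls_path)
  )
}
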