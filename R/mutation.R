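# Mutation evidence: per-gene mutation frequency and the m-index consensus
# over up to five external driver-detection algorithms. The algorithms
# themselves (MutSigCV, OncodriveCLUST, ActiveDriver, iPAC, DriverML) are
# consumed as a call matrix, never re-implemented; for self-contained runs
# a pseudo-caller ensemble stands in.

#' Per-gene mutation frequency
#'
#' Frequency = number of mutated specimens / total specimens. A specimen
#' with several qualifying mutations in one gene counts once; silent
#' variants were already excluded at parse time.
#'
#' @param mutations Mutation tibble (`sample_id`, `gene_id`, ...).
#' @param sample_registry Character vector of specimen ids defining the
#'   denominator, or a tibble with a `sample_id` column.
#' @param panel Optional gene panel (tibble or character vector); genes with
#'   no mutations are reported with frequency 0.
#' @return A tibble (`gene_id`, `n_mutated_samples`, `n_samples`,
#'   `frequency`).
#' @export
#' @examples
#' mut <- tibble::tibble(sample_id = paste0("S", 1:8), gene_id = "CHD7")
#' mutation_frequency(mut, paste0("S", 1:100)) # frequency 0.08
mutation_frequency <- function(mutations, sample_registry, panel = NULL) {
  if (is.data.frame(sample_registry)) {
    sample_registry <- sample_registry$sample_id
  }
  n <- length(sample_registry)
  if (n == 0) abort("mutation_frequency: empty sample registry")
  unknown <- setdiff(mutations$sample_id, sample_registry)
  if (length(unknown) > 0) {
    abort(sprintf(
      "mutation table references unregistered sample(s): %s",
      paste(head(unknown, 5), collapse = ", ")
    ))
  }
  genes <- if (is.null(panel)) {
    sort(unique(mutations$gene_id))
  } else if (is.data.frame(panel)) {
    panel$gene_id
  } else {
    panel
  }
  counts <- mutations |>
    filter(.data$gene_id %in% genes) |>
    distinct(.data$gene_id, .data$sample_id) |>
    count(.data$gene_id, name = "n_mutated_samples")
  tibble(gene_id = genes) |>
    left_join(counts, by = "gene_id") |>
    mutate(
      n_mutated_samples = dplyr::coalesce(.data$n_mutated_samples, 0L),
      n_samples = n,
      frequency = .data$n_mutated_samples / n
    )
}

#' m-index: driver-caller consensus
#'
#' Counts, per gene, how many of the available driver-detection algorithms
#' call it significantly mutated; genes with `m_index >= m_min` (default 2)
#' are flagged significant. When fewer than `m_min` algorithm columns are
#' available the flag is forced `FALSE` and the result is marked
#' insufficient coverage, because the consensus rule cannot be met.
#'
#' @param call_matrix Tibble with `gene_id` and one logical column per
#'   algorithm (at most 5; duplicated algorithm columns are an error).
#' @param m_min Consensus threshold (default 2).
#' @return A tibble (`gene_id`, `m_index`, `n_algorithms`, `significant`,
#'   `coverage`).
#' @export
m_index <- function(call_matrix, m_min = 2L) {
  require_columns(call_matrix, "gene_id", "driver-call matrix")
  algs <- names(call_matrix)[names(call_matrix) != "gene_id"]
  if (length(algs) == 0) abort("m_index: no algorithm columns")
  if (length(algs) > 5) abort("m_index: more than 5 algorithm columns")
  if (anyDuplicated(algs)) abort("m_index: duplicated algorithm column")
  calls <- as.matrix(call_matrix[, algs, drop = FALSE])
  storage.mode(calls) <- "logical"
  enough <- length(algs) >= m_min
  tibble(
    gene_id = call_matrix$gene_id,
    m_index = as.integer(rowSums(calls)),
    n_algorithms = length(algs),
    significant = if (enough) rowSums(calls) >= m_min else FALSE,
    coverage = if (enough) "ok" else "insufficient coverage"
  )
}

#' Pseudo-caller ensemble for self-contained runs
#'
#' Emulates a panel of driver-detection algorithms on top of per-gene
#' mutation counts: caller j flags gene g when the one-sided binomial tail
#' probability `P(X >= n_mutated | n, background_rate)` falls below its
#' alpha_j, after which each call is independently flipped with noise
#' epsilon_j. Deterministic under `seed`. Because all callers test the same
#' statistic, their noise-free calls are nested by alpha.
#'
#' @param freqs Tibble from [mutation_frequency()].
#' @param background_rate Background per-gene-per-specimen mutation rate
#'   (> 0).
#' @param alpha Per-caller significance levels (length = number of
#'   callers, at most 5).
#' @param epsilon Per-caller flip-noise probabilities (recycled).
#' @param seed Integer seed.
#' @param caller_names Optional column names for the emulated callers.
#' @return A gene-by-algorithm logical tibble (a driver-call matrix).
#' @export
pseudo_callers <- function(freqs, background_rate,
                           alpha = c(0.001, 0.005, 0.01, 0.01, 0.05),
                           epsilon = 0.02, seed = 1L,
                           caller_names = NULL) {
  stopifnot(background_rate > 0, length(alpha) <= 5)
  epsilon <- rep_len(epsilon, length(alpha))
  if (is.null(caller_names)) {
    caller_names <- paste0("caller", seq_along(alpha))
  }
  # one-sided upper binomial tail: P(X >= k | n, p0)
  tail_p <- pbinom(freqs$n_mutated_samples - 1L, freqs$n_samples,
                   background_rate, lower.tail = FALSE)
  calls <- withr::with_seed(child_seed(seed, "pseudo-callers"), {
    purrr::map(seq_along(alpha), function(j) {
      base <- tail_p < alpha[j]
      flip <- runif(length(base)) < epsilon[j]
      xor(base, flip)
    })
  })
  out <- tibble(gene_id = freqs$gene_id)
  for (j in seq_along(alpha)) out[[caller_names[j]]] <- calls[[j]]
  out
}

#' Run the full mutation stage on one cohort bundle
#'
#' Computes per-gene frequencies over the tumour specimens and the m-index:
#' from the bundle's external driver-call matrix when present, otherwise
#' from the pseudo-caller ensemble.
#'
#' @param bundle A `cohort_bundle`.
#' @param m_min Consensus threshold.
#' @param background_rate Background rate for the pseudo-callers.
#' @param seed Integer seed (pseudo-caller noise).
#' @return A tibble (`gene_id`, `cancer_type`, `n_mutated_samples`,
#'   `n_samples`, `frequency`, `m_index`, `significant`, `coverage`).
#' @export
mutation_stage <- function(bundle, m_min = 2L, background_rate = 0.01,
                           seed = 1L) {
  samples <- tumour_samples(bundle)
  freqs <- mutation_frequency(bundle$mutations, samples,
                              panel = bundle$gene_model)
  calls <- bundle$driver_calls
  if (is.null(calls)) {
    calls <- pseudo_callers(
      freqs, background_rate,
      seed = child_seed(seed, "mutation", bundle$cancer_type)
    )
  }
  mi <- m_index(calls, m_min = m_min)
  freqs |>
    left_join(mi, by = "gene_id") |>
    mutate(
      m_index = dplyr::coalesce(.data$m_index, 0L),
      n_algorithms = dplyr::coalesce(.data$n_algorithms,
                                     ncol(calls) - 1L),
      significant = dplyr::coalesce(.data$significant, FALSE),
      coverage = dplyr::coalesce(.data$coverage, "not in call matrix"),
      cancer_type = bundle$cancer_type
    ) |>
    select("gene_id", "cancer_type", "n_mutated_samples", "n_samples",
           "frequency", "m_index", "n_algorithms", "significant", "coverage")
}
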