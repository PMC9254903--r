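# Survival evidence: univariate proportional-hazards association of gene
# expression with overall survival, and the good/poor prognosis
# classification (p < 0.1 with HR > 1 poor, HR < 1 good).

#' Univariate proportional-hazards fit of one expression vector
#'
#' Fits a Cox proportional-hazards model of overall survival on one gene's
#' expression: the covariate is the standardized `log2(FPKM + 1)` (so the
#' hazard ratio is per 1 SD of log-expression), or a median-dichotomized
#' 0/1 indicator with `covariate = "median"`. Ties are handled with the
#' Breslow approximation and the p-value is the two-sided Wald test.
#' Cohorts with fewer than `min_n` samples or `min_events` events, and
#' constant covariates, are reported unevaluable rather than fitted;
#' monotone likelihood (e.g. perfect separation of event order by
#' expression) is flagged, never silently returned.
#'
#' @param expression_vector Named numeric FPKM vector (names = sample ids).
#' @param clinical Clinical tibble (`sample_id`, `os_time`, `os_event`).
#' @param covariate `"continuous"` (default) or `"median"`.
#' @param min_n,min_events Evaluability floor (defaults 20 samples,
#'   5 events).
#' @return A one-row tibble (`hr`, `log_hr`, `se`, `p`, `n`, `n_events`,
#'   `evaluable`, `monotone_flag`, `reason`).
#' @export
fit_univariate_ph <- function(expression_vector, clinical,
                              covariate = c("continuous", "median"),
                              min_n = 20L, min_events = 5L) {
  covariate <- match.arg(covariate)
  shared <- intersect(names(expression_vector), clinical$sample_id)
  cl <- clinical[match(shared, clinical$sample_id), ]
  ph_fit_core(
    log2(expression_vector[shared] + 1),
    survival::Surv(cl$os_time, cl$os_event),
    sum(cl$os_event), covariate, min_n, min_events,
    survival::coxph.control()
  )
}

# Shared fitting core over an aligned covariate (log2(FPKM + 1) scale)
# and a prebuilt Surv object.
ph_fit_core <- function(x_raw, y, n_events, covariate, min_n, min_events,
                        ctrl) {
  n <- length(x_raw)
  unevaluable <- function(reason) {
    tibble(
      hr = NA_real_, log_hr = NA_real_, se = NA_real_, p = NA_real_,
      n = n, n_events = n_events, evaluable = FALSE,
      monotone_flag = FALSE, reason = reason
    )
  }
  if (n < min_n || n_events < min_events) {
    return(unevaluable(sprintf(
      "insufficient data (n = %d, events = %d)", n, n_events
    )))
  }
  s <- sd(x_raw)
  if (s == 0) return(unevaluable("constant covariate"))
  x <- if (covariate == "continuous") {
    (x_raw - mean(x_raw)) / s
  } else {
    as.numeric(x_raw > median(x_raw))
  }
  if (sd(x) == 0) return(unevaluable("constant covariate"))
  fit_warning <- NULL
  fit <- tryCatch(
    withCallingHandlers(
      survival::coxph.fit(
        matrix(x, ncol = 1), y,
        strata = NULL, offset = NULL, init = 0,
        control = ctrl, weights = NULL,
        method = "breslow", rownames = NULL
      ),
      warning = function(w) {
        fit_warning <<- conditionMessage(w)
        invokeRestart("muffleWarning")
      }
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || is.null(fit$coefficients)) {
    return(unevaluable("fit failed"))
  }
  beta <- unname(fit$coefficients)
  se <- sqrt(unname(fit$var[1, 1]))
  # monotone partial likelihood drives |beta| off to infinity; flag it
  monotone <- !is.finite(beta) || !is.finite(se) ||
    abs(beta) > 10 || se > 100 ||
    (!is.null(fit_warning) && grepl("converge", fit_warning))
  z <- beta / se
  tibble(
    hr = exp(beta), log_hr = beta, se = se,
    p = 2 * pnorm(-abs(z)),
    n = n, n_events = n_events, evaluable = TRUE,
    monotone_flag = monotone,
    reason = if (monotone) "monotone likelihood" else "fitted"
  )
}

#' Classify prognosis from a hazard ratio and p-value
#'
#' `poor` when `p < p_threshold` and HR > 1; `good` when `p < p_threshold`
#' and HR < 1; otherwise `none`. The survival evidence flag used for
#' scoring is `prognosis != "none"` (good-or-poor prediction).
#'
#' @param hr Hazard ratio (> 0).
#' @param p Two-sided p-value.
#' @param p_threshold Significance gate (default 0.1).
#' @return Character vector in `{poor, good, none}` (vectorized).
#' @export
#' @examples
#' classify_prognosis(c(1.8, 0.6, 2.5), c(0.03, 0.08, 0.2))
classify_prognosis <- function(hr, p, p_threshold = 0.1) {
  dplyr::case_when(
    is.na(hr) | is.na(p) ~ "none",
    p < p_threshold & hr > 1 ~ "poor",
    p < p_threshold & hr < 1 ~ "good",
    .default = "none"
  )
}

#' Run the full survival stage on one cohort bundle
#'
#' Per-gene univariate proportional-hazards fits over the tumour samples
#' with clinical follow-up, plus the prognosis classification. The raw
#' p-value is gated at `p_threshold` without multiple-testing correction;
#' a BH-adjusted column is emitted alongside for transparency.
#'
#' @param bundle A `cohort_bundle`.
#' @param p_threshold Prognosis significance gate (default 0.1).
#' @param covariate `"continuous"` or `"median"`.
#' @return A tibble (`gene_id`, `cancer_type`, `hr`, `p`, `q_bh`, `n`,
#'   `n_events`, `prognosis`, `evaluable`, `reason`).
#' @export
survival_stage <- function(bundle, p_threshold = 0.1,
                           covariate = "continuous") {
  values <- bundle$expression$values
  samples <- intersect(tumour_samples(bundle), bundle$clinical$sample_id)
  m <- as.matrix(values[, samples, drop = FALSE])
  rownames(m) <- values$gene_id
  cl <- bundle$clinical[match(samples, bundle$clinical$sample_id), ]
  y <- survival::Surv(cl$os_time, cl$os_event)
  ctrl <- survival::coxph.control()
  fits <- purrr::map(seq_len(nrow(m)), function(i) {
    ph_fit_core(log2(m[i, ] + 1), y, sum(cl$os_event), covariate, 20L,
                5L, ctrl)
  })
  out <- bind_rows(fits)
  out$gene_id <- values$gene_id
  out$cancer_type <- bundle$cancer_type
  out$q_bh <- bh_adjust(out$p)
  out$prognosis <- classify_prognosis(out$hr, out$p, p_threshold)
  select(out, "gene_id", "cancer_type", "hr", "log_hr", "se", "p", "q_bh",
         "n", "n_events", "prognosis", "evaluable", "monotone_flag",
         "reason")
}
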