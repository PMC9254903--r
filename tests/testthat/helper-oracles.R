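# Independent oracles used by the unit and acceptance tests. These stay
# deliberately naive (full enumeration) and share no code with the
# package's own implementations.

# Exact two-sided signed-rank p by exhaustive enumeration over all 2^n
# sign assignments (zeros dropped, midranks for tied |d|).
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  v_all <- apply(as.matrix(signs), 1, function(pos) sum(r[pos]))
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Exact pooled permutation null of the G-score for a small matrix: under
# independent per-column permutations each row's null entries are uniform
# draws from the column's values, so the pooled (row-marginal) null is the
# full enumeration over one value per column.
enum_pooled_gscore_null <- function(m, theta, direction = "amp") {
  cols <- lapply(seq_len(ncol(m)), function(j) m[, j])
  combos <- as.matrix(expand.grid(cols))
  x <- if (direction == "amp") combos else -combos
  rowMeans(pmax(x - theta, 0))
}

# Small single-cancer simulation config used across tests.
tiny_sim_config <- function(...) {
  simulation_config(
    n_cancer_types = 1, n_tumour = 40, n_normal_pairs = 12,
    n_decoys = 20, ...
  )
}

# Paired tumour/normal expression object built directly from a matrix of
# tumour and normal FPKM values (genes x pairs).
make_paired_expression <- function(tum, nor, genes = NULL) {
  n_pairs <- ncol(tum)
  if (is.null(genes)) genes <- sprintf("G%03d", seq_len(nrow(tum)))
  pts <- sprintf("P%03d", seq_len(n_pairs))
  vals <- dplyr::bind_cols(
    tibble::tibble(gene_id = genes),
    tibble::as_tibble(stats::setNames(as.data.frame(tum),
                                      paste0(pts, "-T"))),
    tibble::as_tibble(stats::setNames(as.data.frame(nor),
                                      paste0(pts, "-N")))
  )
  meta <- tibble::tibble(
    sample_id = c(paste0(pts, "-T"), paste0(pts, "-N")),
    patient_id = rep(pts, 2),
    tissue = rep(c("tumour", "normal"), each = n_pairs)
  )
  list(values = vals, sample_meta = meta)
}

# Long gene-CN tibble from a genes x samples matrix.
make_gene_cn <- function(m) {
  tibble::tibble(
    gene_id = rep(rownames(m), times = ncol(m)),
    sample_id = rep(colnames(m), each = nrow(m)),
    log2_ratio = as.vector(m)
  )
}
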