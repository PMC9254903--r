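# Internal helpers shared across stages.

#' Derive a reproducible child seed from a master seed and a stream label
#'
#' All stochastic layers of the simulator (and the permutation null of the
#' copy-number stage) draw from streams whose seeds are derived
#' deterministically from one master seed, so that disabling one layer never
#' perturbs the draws of another.
#'
#' @param seed Integer master seed.
#' @param ... Character or numeric labels identifying the stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' child_seed(1L, "expression", "C01")
child_seed <- function(seed, ...) {
  labels <- paste(c(...), collapse = "/")
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(labels)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Normalize chromosome names: accept with/without "chr" prefix, keep
# a canonical "chr"-prefixed form; case-insensitive for X/Y/M.
normalize_chrom <- function(x) {
  x <- as.character(x)
  x <- sub("^[Cc][Hh][Rr]", "", x)
  x <- toupper(x)
  x <- sub("^MT$", "M", x)
  paste0("chr", x)
}

# Format a numeric column at 6 significant digits for deterministic TSV
# output; integers and non-numerics pass through unchanged.
format_sig6 <- function(x) {
  if (is.double(x)) {
    out <- formatC(signif(x, 6), format = "g", digits = 6)
    out[is.na(x)] <- "NA"
    out
  } else {
    x
  }
}

# Stop unless all `cols` are present, naming the offenders.
require_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing mandatory column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Benjamini-Hochberg adjustment; thin wrapper kept for a single point of
# change should the panel-level correction ever become configurable.
bh_adjust <- function(p) p.adjust(p, method = "BH")
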