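#' @keywords internal
"_PACKAGE"

# log2(TPM + 1), the expression scale used throughout the analysis stages
log2p1 <- function(x) log2(x + 1)

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != floor(x))
    stop_invalid("'%s' must be a single integer >= %d", name, min)
  as.integer(x)
}

check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_invalid("'%s' must lie in [0, 1]", name)
  x
}

# Expression matrices are plain numeric matrices, genes in rows, samples in
# columns, with dimnames required by every downstream join.
check_expression_matrix <- function(x, name = "expr") {
  if (!is.matrix(x) || !is.numeric(x))
    stop_invalid("'%s' must be a numeric matrix (genes x samples)", name)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop_invalid("'%s' must carry gene rownames and sample colnames", name)
  invisible(x)
}

# Renormalize each column to TPM scale (1e6 total)
renorm_tpm <- function(x) {
  cs <- colSums(x)
  if (any(cs <= 0)) stop_invalid("cannot TPM-normalize a zero column")
  sweep(x, 2L, cs / 1e6, "/")
}
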