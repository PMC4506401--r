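#' Principal component analysis of an expression subset
#'
#' PCA of samples on log2(TPM+1), gene-centered (no scaling), via
#' `prcomp`. Component signs are fixed deterministically by forcing the
#' largest-magnitude loading of each component positive, so scores are
#' reproducible across runs and platforms.
#'
#' @param expr genes x samples TPM matrix (e.g. restricted to
#'   discriminating genes).
#' @param log_transform apply log2(TPM+1) (default TRUE; set FALSE for
#'   pre-transformed input).
#' @param pool_groups optional per-sample group labels. When given, the
#'   stored pooling gap is the cell-weighted mean of within-group gaps
#'   — the gap expected when a bulk pools cells of one subclone. A
#'   mixed-clone bulk then retains the between-clone part of the gap
#'   and projects toward its dominant contributors, which is the
#'   biologically expected behavior. Without labels the gap is computed
#'   over all cells (exact for a full-population pool).
#' @return object of class `sc_pca`: `loadings` (genes x components,
#'   orthonormal), `scores` (samples x components), `var_fraction`
#'   (sums to 1), `center` (training gene means on the transformed
#'   scale), `log_transform`, and `pool_offset` — the per-gene Jensen
#'   gap `log2(mean TPM + 1) - mean(log2(TPM + 1))` of the training
#'   cells, used by [project_bulk()] to place pooled-population bulks
#'   on the single-cell log scale.
#' @export
pca_expression <- function(expr, log_transform = TRUE,
                           pool_groups = NULL) {
  check_expression_matrix(expr)
  if (nrow(expr) < 2 || ncol(expr) < 2)
    stop_invalid("PCA needs at least 2 genes and 2 samples")
  x <- if (log_transform) log2p1(expr) else expr
  if (all(apply(x, 1L, stats::sd) == 0))
    stop_invalid("degenerate input: no gene varies across samples")
  fit <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  # deterministic sign: largest-|loading| entry of each PC is positive
  flip <- vapply(seq_len(ncol(fit$rotation)), function(k) {
    v <- fit$rotation[, k]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  loadings <- sweep(fit$rotation, 2L, flip, "*")
  scores <- sweep(fit$x, 2L, flip, "*")
  gap <- function(m) log2p1(rowMeans(m)) - rowMeans(log2p1(m))
  pool_offset <- if (!log_transform) {
    stats::setNames(numeric(nrow(expr)), rownames(expr))
  } else if (is.null(pool_groups)) {
    gap(expr)
  } else {
    if (length(pool_groups) != ncol(expr))
      stop_invalid("'pool_groups' must label every sample")
    keep <- !is.na(pool_groups)
    grp <- split(which(keep), pool_groups[keep])
    grp <- grp[vapply(grp, length, 1L) >= 2L]
    if (length(grp) == 0) gap(expr) else {
      w <- vapply(grp, length, 1L)
      gaps <- vapply(grp, function(j) gap(expr[, j, drop = FALSE]),
                     numeric(nrow(expr)))
      drop(gaps %*% (w / sum(w)))
    }
  }
  out <- list(loadings = loadings, scores = scores,
              var_fraction = fit$sdev^2 / sum(fit$sdev^2),
              center = fit$center, log_transform = log_transform,
              pool_offset = pool_offset)
  class(out) <- "sc_pca"
  out
}

#' @export
print.sc_pca <- function(x, ...) {
  cat(sprintf("PCA: %d genes, %d samples; PC1/PC2 variance %.1f%% / %.1f%%\n",
              nrow(x$loadings), nrow(x$scores),
              100 * x$var_fraction[1], 100 * x$var_fraction[2]))
  invisible(x)
}

#' @export
predict.sc_pca <- function(object, newdata, n_components = NULL, ...) {
  project_bulk(newdata, object, n_components = n_components)
}
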