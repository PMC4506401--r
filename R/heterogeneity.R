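#' Pairwise expression correlation between single cells
#'
#' Correlation of log2(TPM+1) profiles for every cell pair, the
#' cell-to-cell heterogeneity readout whose density is compared across
#' populations.
#'
#' @param cells genes x cells TPM matrix.
#' @param method "pearson" or "spearman".
#' @param log_transform apply log2(TPM+1) first (default TRUE; set FALSE
#'   if `cells` is already on log scale).
#' @return list with `matrix` (symmetric, unit diagonal; pairs involving
#'   a zero-variance cell are NA), `values` (flat vector of defined
#'   off-diagonal coefficients, lower triangle), and `undefined_cells`
#'   (cells with zero variance, whose pairs are flagged undefined).
#' @examples
#' m <- matrix(c(1, 2, 3, 2, 4, 6), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("a", "b")))
#' pairwise_expression_correlation(m, log_transform = FALSE)$matrix
#' @export
pairwise_expression_correlation <- function(cells,
                                            method = c("pearson", "spearman"),
                                            log_transform = TRUE) {
  method <- match.arg(method)
  check_expression_matrix(cells, "cells")
  if (ncol(cells) < 2L) stop_invalid("need at least 2 cells")
  x <- if (log_transform) log2p1(cells) else cells
  sds <- apply(x, 2L, stats::sd)
  flat_cells <- colnames(x)[sds == 0]
  r <- suppressWarnings(stats::cor(x, method = method))
  r[, flat_cells] <- NA_real_
  r[flat_cells, ] <- NA_real_
  diag(r) <- 1
  vals <- r[lower.tri(r)]
  list(matrix = r, values = vals[!is.na(vals)],
       undefined_cells = flat_cells)
}

#' Explanatory power of pooled single cells for the bulk profile
#'
#' For each permutation, samples `n` cells without replacement and
#' regresses the bulk log-expression on the `n` single-cell
#' log-profiles plus an intercept, across genes. The recorded statistic
#' is the adjusted R-squared
#' `1 - (1 - R^2) (N - 1) / (N - n - 1)` with `N` the number of genes
#' used, so pools approaching the bulk give values near 1.
#'
#' @param cells genes x cells TPM matrix.
#' @param bulk named bulk TPM vector on the same gene index.
#' @param n pool size (number of regressor cells).
#' @param n_perm number of permutations.
#' @param seed RNG seed; same seed gives identical results.
#' @param log_transform apply log2(TPM+1) to both inputs (default TRUE).
#' @param intercept include an intercept (default TRUE).
#' @return data.frame of class `saturation_result` entry: columns `n`,
#'   `perm`, `value`; attributes `n_perm`, `seed`, `n_genes_used`,
#'   `n_genes_dropped` (genes zero in all cells and the bulk are dropped
#'   before the fit).
#' @export
pooled_explanatory_power <- function(cells, bulk, n, n_perm = 1000L,
                                     seed = 1L, log_transform = TRUE,
                                     intercept = TRUE) {
  check_expression_matrix(cells, "cells")
  if (is.null(names(bulk))) stop_invalid("'bulk' must be a named vector")
  common <- intersect(rownames(cells), names(bulk))
  if (length(common) == 0) stop_invalid("cells and bulk share no genes")
  x_all <- cells[common, , drop = FALSE]
  y_all <- bulk[common]
  keep <- rowSums(x_all) > 0 | y_all > 0
  x_all <- x_all[keep, , drop = FALSE]
  y_all <- y_all[keep]
  if (log_transform) {
    x_all <- log2p1(x_all)
    y_all <- log2p1(y_all)
  }
  N <- nrow(x_all)
  n <- check_count(n, "n", min = 1L)
  if (n > ncol(x_all)) stop_invalid("pool size n exceeds the cell count")
  p <- n + as.integer(intercept)
  if (N - p < 1L || n >= N - 1L)
    stop_invalid("ill-posed regression: %d genes cannot support %d regressors",
                 N, n)

  set.seed(seed)
  vals <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(ncol(x_all), n)
    X <- x_all[, idx, drop = FALSE]
    if (intercept) X <- cbind(`(Intercept)` = 1, X)
    fit <- stats::lm.fit(X, y_all)
    rss <- sum(fit$residuals^2)
    tss <- sum((y_all - mean(y_all))^2)
    r2 <- if (tss == 0) 1 else 1 - rss / tss
    1 - (1 - r2) * (N - 1) / (N - n - 1)
  }, numeric(1))

  out <- data.frame(n = n, perm = seq_len(n_perm), value = vals)
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "n_genes_used") <- N
  attr(out, "n_genes_dropped") <- sum(!keep)
  class(out) <- c("saturation_result", "data.frame")
  out
}

# MUT_EXPRESSED variant sets per cell, NO_CALL excluded from both sides
mut_sets <- function(genotypes) {
  calls <- if (inherits(genotypes, "cell_genotype_matrix"))
    genotypes$calls else genotypes
  stats::setNames(lapply(seq_len(ncol(calls)), function(j)
    rownames(calls)[calls[, j] == "MUT_EXPRESSED" & !is.na(calls[, j])]),
    colnames(calls))
}

#' Pairwise overlap of expressed SNV sets between single cells
#'
#' For each cell pair, the Jaccard ratio of the MUT_EXPRESSED variant
#' sets: `|S_i & S_j| / |S_i | S_j|` (NO_CALL sites contribute to
#' neither set). The alternative normalization by the smaller set is
#' available via `normalize = "min"`.
#'
#' @param genotypes a `cell_genotype_matrix` (see
#'   [call_cell_genotypes()]) or a character call matrix.
#' @param normalize "union" (Jaccard, default) or "min" (intersection
#'   over the smaller set).
#' @return list with `matrix` (cells x cells; pairs with an empty union
#'   are NA), `values` (defined off-diagonal ratios), and
#'   `n_undefined_pairs`.
#' @export
expressed_snv_overlap <- function(genotypes, normalize = c("union", "min")) {
  normalize <- match.arg(normalize)
  sets <- mut_sets(genotypes)
  k <- length(sets)
  if (k < 2L) stop_invalid("need at least 2 cells")
  m <- matrix(NA_real_, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      inter <- length(intersect(sets[[i]], sets[[j]]))
      denom <- switch(normalize,
                      union = length(union(sets[[i]], sets[[j]])),
                      min = min(length(sets[[i]]), length(sets[[j]])))
      m[i, j] <- if (denom == 0) NA_real_ else inter / denom
    }
  }
  vals <- m[lower.tri(m)]
  list(matrix = m, values = vals[!is.na(vals)],
       n_undefined_pairs = sum(is.na(vals)))
}

#' Saturation of the pooled expressed-SNV union against the bulk set
#'
#' Per permutation, samples `n` cells without replacement and computes
#' the fraction of the bulk SNV set covered by the union of the pooled
#' cells' MUT_EXPRESSED sets:
#' `|union_i S_i & bulk| / |bulk|`.
#'
#' @param genotypes a `cell_genotype_matrix` or call matrix.
#' @param bulk_snvs non-empty character vector of bulk variant ids.
#' @param n pool size.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return `saturation_result` data.frame entry (columns n, perm, value).
#' @export
snv_union_saturation <- function(genotypes, bulk_snvs, n, n_perm = 1000L,
                                 seed = 1L) {
  if (length(bulk_snvs) == 0) stop_invalid("'bulk_snvs' must be non-empty")
  sets <- mut_sets(genotypes)
  n <- check_count(n, "n", min = 1L)
  if (n > length(sets))
    stop_invalid("pool size n = %d exceeds the %d cells", n, length(sets))
  bulk_snvs <- unique(bulk_snvs)

  set.seed(seed)
  vals <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(sets), n)
    pooled <- unique(unlist(sets[idx], use.names = FALSE))
    length(intersect(pooled, bulk_snvs)) / length(bulk_snvs)
  }, numeric(1))

  out <- data.frame(n = n, perm = seq_len(n_perm), value = vals)
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  class(out) <- c("saturation_result", "data.frame")
  out
}

#' Saturation curve over a grid of pool sizes
#'
#' Convenience wrapper running [pooled_explanatory_power()] or
#' [snv_union_saturation()] over `n_grid` and stacking the entries.
#'
#' @param n_grid pool sizes (e.g. `c(5, 15, 25, 34, 50)`).
#' @param fun the single-size statistic function.
#' @param ... passed to `fun` (everything except `n`).
#' @return stacked `saturation_result` data.frame.
#' @export
saturation_curve <- function(n_grid, fun, ...) {
  out <- do.call(rbind, lapply(n_grid, function(n) fun(n = n, ...)))
  class(out) <- c("saturation_result", "data.frame")
  out
}

#' Summarize a saturation result
#'
#' Mean and 10th/90th percentiles per pool size (the whisker convention
#' used for saturation boxplots).
#'
#' @param object a `saturation_result`.
#' @param ... unused.
#' @return data.frame with n, mean, q10, q90.
#' @export
summary.saturation_result <- function(object, ...) {
  agg <- function(v) c(mean = mean(v),
                       q10 = unname(stats::quantile(v, 0.10)),
                       q90 = unname(stats::quantile(v, 0.90)))
  res <- do.call(rbind, lapply(split(object$value, object$n), agg))
  data.frame(n = as.integer(rownames(res)), res, row.names = NULL)
}
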