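#' Project bulk profiles into the single-cell PC space
#'
#' Applies the frozen single-cell PCA fit to bulk samples: the same
#' log2(TPM+1) transform, centering by the training gene means, and
#' multiplication by the stored loadings. The loadings are never refit
#' on bulk data.
#'
#' A bulk profile is a (weighted) mean of cell TPM profiles, so its
#' log transform carries a per-gene convexity gap relative to the mean
#' of the cells' log profiles: log2(mean TPM + 1) exceeds
#' mean(log2(TPM + 1)) by roughly half the cell-to-cell variance. With
#' `pool_correction = TRUE` the gap estimated from the training cells
#' (`pca_fit$pool_offset`) is subtracted before projection, placing
#' pooled populations on the single-cell log scale; leave it `FALSE`
#' when the projected sample is itself a single-cell-scale profile.
#'
#' @param bulk named TPM vector or genes x samples matrix covering the
#'   fit's gene index (missing genes raise an error naming them).
#' @param pca_fit an `sc_pca` from [pca_expression()].
#' @param n_components number of components to keep (default: all).
#' @param pool_correction subtract the training-cell pooling gap
#'   (default FALSE).
#' @return samples x components coordinate matrix.
#' @export
project_bulk <- function(bulk, pca_fit, n_components = NULL,
                         pool_correction = FALSE) {
  stopifnot(inherits(pca_fit, "sc_pca"))
  if (is.null(dim(bulk))) bulk <- matrix(bulk, ncol = 1,
                                         dimnames = list(names(bulk), "bulk"))
  genes <- rownames(pca_fit$loadings)
  missing <- setdiff(genes, rownames(bulk))
  if (length(missing) > 0)
    stop_invalid("bulk lacks fitted genes: %s",
                 paste(utils::head(missing, 10), collapse = ", "))
  x <- bulk[genes, , drop = FALSE]
  if (pca_fit$log_transform) x <- log2p1(x)
  if (pool_correction) x <- x - pca_fit$pool_offset[genes]
  k <- if (is.null(n_components)) ncol(pca_fit$loadings)
       else min(n_components, ncol(pca_fit$loadings))
  t(x - pca_fit$center) %*% pca_fit$loadings[, seq_len(k), drop = FALSE]
}

#' Train a C-SVM subgroup classifier on single-cell PC scores
#'
#' Soft-margin C-classification SVM (one-vs-one multiclass, via e1071)
#' in the single-cell PC space, used to assign bulk samples to the
#' subgroup whose signature they resemble. Defaults follow the cited
#' implementation's: radial kernel, cost 1, kernel width
#' 1/n_components, inputs standardized. Standardization uses the
#' population (1/n) standard deviation so that duplicating every
#' training point leaves the decision boundary exactly unchanged.
#'
#' @param scores samples x components PC score matrix (training cells).
#' @param groups per-cell subgroup labels.
#' @param n_components components used (default 2, the PC1-PC2 plane).
#' @param kernel,cost,gamma SVM hyperparameters (gamma defaults to
#'   1/n_components).
#' @return object of class `group_classifier`: the fitted SVM,
#'   `n_components`, `levels`, `training_accuracy`.
#' @export
train_group_classifier <- function(scores, groups, n_components = 2L,
                                   kernel = "radial", cost = 1,
                                   gamma = NULL) {
  keep <- !is.na(groups)
  scores <- scores[keep, , drop = FALSE]
  groups <- groups[keep]
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2))
    stop_invalid("need >= 2 groups with >= 2 cells each (got %s)",
                 paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  k <- min(n_components, ncol(scores))
  x <- scores[, seq_len(k), drop = FALSE]
  if (is.null(gamma)) gamma <- 1 / k
  y <- factor(groups)
  ctr <- colMeans(x)
  scl <- sqrt(colMeans(sweep(x, 2L, ctr)^2))
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  fit <- e1071::svm(xs, y, type = "C-classification", kernel = kernel,
                    cost = cost, gamma = gamma, scale = FALSE)
  out <- list(svm = fit, n_components = k, levels = levels(y),
              center = ctr, scale = scl,
              training_accuracy = mean(stats::predict(fit, xs) == y))
  class(out) <- "group_classifier"
  out
}

#' @export
print.group_classifier <- function(x, ...) {
  cat(sprintf("Subgroup C-SVM: %d PCs, groups %s, training accuracy %.1f%%\n",
              x$n_components, paste(x$levels, collapse = "/"),
              100 * x$training_accuracy))
  invisible(x)
}

#' Classify projected samples into single-cell subgroups
#'
#' @param classifier a `group_classifier`.
#' @param coords samples x components coordinates from
#'   [project_bulk()] (at least `n_components` columns).
#' @return data.frame `sample`, `group` (always one of the training
#'   labels), plus decision-value columns for audit.
#' @export
classify_samples <- function(classifier, coords) {
  stopifnot(inherits(classifier, "group_classifier"))
  if (ncol(coords) < classifier$n_components)
    stop_invalid("coordinates have %d components; classifier needs %d",
                 ncol(coords), classifier$n_components)
  x <- coords[, seq_len(classifier$n_components), drop = FALSE]
  x <- sweep(sweep(x, 2L, classifier$center), 2L, classifier$scale, "/")
  pred <- stats::predict(classifier$svm, x, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  out <- data.frame(sample = rownames(x), group = as.character(pred),
                    stringsAsFactors = FALSE, row.names = NULL)
  cbind(out, as.data.frame(dv))
}

#' @export
predict.group_classifier <- function(object, coords, ...) {
  classify_samples(object, coords)
}
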