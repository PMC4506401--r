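#' Filter a marker panel against a single-cell matrix
#'
#' Retains markers that are present in the matrix and have nonzero
#' expression in at least one cell — the gene filtering that reduced the
#' published marker panel to its final 69 genes.
#'
#' @param markers candidate marker gene IDs.
#' @param cells genes x cells TPM matrix.
#' @return the retained marker IDs.
#' @export
filter_marker_genes <- function(markers, cells) {
  check_expression_matrix(cells, "cells")
  present <- intersect(markers, rownames(cells))
  kept <- present[rowSums(cells[present, , drop = FALSE] > 0) > 0]
  if (length(kept) == 0)
    stop_invalid("no usable markers: all absent or zero across cells")
  kept
}

#' Train a prognostic risk-score model
#'
#' Fits a univariate Cox proportional-hazards model per marker gene on
#' the training cohort, stores the per-gene coefficients and Wald
#' p-values (genes ordered by p for display), computes each training
#' sample's risk score `RS_j = sum_g beta_g x_gj`, and learns the
#' normalization offset as the `cutoff_percentile` quantile of the
#' training scores (linear-interpolation quantile). Samples with
#' normalized RS > 0 — the top (100 - cutoff)% — are the high-risk
#' class.
#'
#' @param cohort a `survival_cohort` (or list with `expression`, `time`,
#'   `event`).
#' @param markers marker genes; default all genes in the cohort matrix.
#' @param cells optional single-cell TPM matrix: when supplied, markers
#'   are first reduced with [filter_marker_genes()].
#' @param cutoff_percentile percentile cutoff (default 60).
#' @return object of class `risk_model`: marker genes, `beta`, `se`,
#'   `p`, `ordering` (genes by ascending p), `cutoff_percentile`,
#'   `offset`, `training_scores`, `converged` flags.
#' @seealso [compute_risk_scores()], [normalize_and_classify()],
#'   [score_cells()]
#' @export
train_risk_model <- function(cohort, markers = NULL, cells = NULL,
                             cutoff_percentile = 60) {
  expr <- cohort$expression
  check_expression_matrix(expr, "cohort$expression")
  if (is.null(markers)) markers <- rownames(expr)
  if (!is.null(cells)) markers <- filter_marker_genes(markers, cells)
  markers <- intersect(markers, rownames(expr))
  if (length(markers) == 0) stop_invalid("no markers present in the cohort")
  # genes with zero variance in the cohort cannot be fit
  usable <- markers[apply(expr[markers, , drop = FALSE], 1L, stats::sd) > 0]
  if (length(usable) == 0)
    stop_invalid("no marker varies across the cohort")

  fits <- lapply(usable, function(g)
    fit_univariate_cox(expr[g, ], cohort$time, cohort$event))
  beta <- vapply(fits, `[[`, numeric(1), "beta")
  se <- vapply(fits, `[[`, numeric(1), "se")
  p <- vapply(fits, `[[`, numeric(1), "p")
  conv <- vapply(fits, `[[`, logical(1), "converged")
  names(beta) <- names(se) <- names(p) <- names(conv) <- usable

  model <- list(genes = usable, beta = beta, se = se, p = p,
                ordering = usable[order(p)], converged = conv,
                cutoff_percentile = cutoff_percentile)
  class(model) <- "risk_model"
  rs <- compute_risk_scores(expr, model)
  model$offset <- unname(stats::quantile(rs, cutoff_percentile / 100,
                                         type = 7))
  model$training_scores <- rs
  model
}

#' Risk scores as a linear combination of marker expression
#'
#' `RS_j = sum_g beta_g x_gj` over the model's marker genes.
#'
#' @param expr genes x samples expression matrix containing every model
#'   gene (missing genes raise an error naming them).
#' @param model a `risk_model`.
#' @return named per-sample score vector.
#' @export
compute_risk_scores <- function(expr, model) {
  stopifnot(inherits(model, "risk_model"))
  check_expression_matrix(expr)
  missing <- setdiff(model$genes, rownames(expr))
  if (length(missing) > 0)
    stop_invalid("expression matrix lacks model genes: %s",
                 paste(missing, collapse = ", "))
  drop(crossprod(expr[model$genes, , drop = FALSE], model$beta))
}

#' @export
predict.risk_model <- function(object, expr, ...) {
  compute_risk_scores(expr, object)
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("Prognostic risk model: %d marker genes (univariate Cox)\n",
              length(x$genes)))
  cat(sprintf("  cutoff percentile: %g; training offset: %.4f\n",
              x$cutoff_percentile, x$offset))
  cat(sprintf("  top genes by p: %s\n",
              paste(utils::head(x$ordering, 5), collapse = ", ")))
  if (any(!x$converged))
    cat(sprintf("  %d non-converged gene fit(s)\n", sum(!x$converged)))
  invisible(x)
}

#' @export
summary.risk_model <- function(object, ...) {
  data.frame(gene = object$ordering,
             beta = object$beta[object$ordering],
             se = object$se[object$ordering],
             p = object$p[object$ordering],
             row.names = NULL)
}

#' @export
coef.risk_model <- function(object, ...) object$beta

#' Normalize risk scores and classify high/low risk
#'
#' Normalized RS = RS - offset, where the offset is the
#' `cutoff_percentile` quantile of the reference scores: the scores
#' themselves (`offset_source = "self"`) or a training-derived offset
#' value. High risk iff normalized RS > 0 (strictly), i.e. the top
#' (100 - cutoff)% of the reference distribution.
#'
#' @param scores per-sample risk scores.
#' @param cutoff_percentile percentile cutoff (default 60).
#' @param offset_source "self" or a numeric training offset.
#' @return data.frame with `sample`, `score`, `normalized`, `label`
#'   ("HIGH"/"LOW"); attribute `offset`.
#' @examples
#' normalize_and_classify(stats::setNames(1:10, letters[1:10]))
#' @export
normalize_and_classify <- function(scores, cutoff_percentile = 60,
                                   offset_source = "self") {
  if (identical(offset_source, "self")) {
    if (length(scores) < 2)
      stop_invalid("self-offset needs at least 2 samples")
    offset <- unname(stats::quantile(scores, cutoff_percentile / 100,
                                     type = 7))
  } else {
    if (!is.numeric(offset_source) || length(offset_source) != 1)
      stop_invalid("'offset_source' must be \"self\" or a single number")
    offset <- offset_source
  }
  normalized <- scores - offset
  out <- data.frame(
    sample = if (is.null(names(scores))) seq_along(scores) else names(scores),
    score = unname(scores), normalized = unname(normalized),
    label = ifelse(normalized > 0, "HIGH", "LOW"),
    stringsAsFactors = FALSE)
  attr(out, "offset") <- offset
  out
}

#' Location-scale batch adjustment between two expression matrices
#'
#' Per gene, each batch is standardized to zero mean and unit variance
#' and rescaled to the common location and scale — the average of the
#' two batch means and the root-mean of the two batch variances — so
#' identical batches pass through unchanged (a simplified,
#' non-empirical-Bayes adjustment). Genes with zero variance inside a
#' batch are passed through centered to the common mean.
#'
#' @param expr_a,expr_b genes x samples matrices on a shared gene index.
#' @return list with adjusted `a` and `b`.
#' @export
batch_adjust <- function(expr_a, expr_b) {
  genes <- intersect(rownames(expr_a), rownames(expr_b))
  if (length(genes) == 0) stop_invalid("batches share no genes")
  a <- expr_a[genes, , drop = FALSE]
  b <- expr_b[genes, , drop = FALSE]
  mu_a <- rowMeans(a); mu_b <- rowMeans(b)
  sd_a <- apply(a, 1L, stats::sd); sd_b <- apply(b, 1L, stats::sd)
  pm <- (mu_a + mu_b) / 2
  psd <- sqrt((sd_a^2 + sd_b^2) / 2)
  rescale <- function(m, mu, sd) {
    z <- (m - mu) / ifelse(sd > 0, sd, 1)
    z * ifelse(sd > 0, psd, 0) + pm
  }
  list(a = rescale(a, mu_a, sd_a), b = rescale(b, mu_b, sd_b))
}


#' Score single cells with a patient-trained risk model
#'
#' Default scoring path for cells: batch-adjust the cells against the
#' training cohort ([batch_adjust()]), recompute the training offset on
#' the adjusted cohort, and classify the cells with that
#' training-derived offset (the cutoff is not re-derived on the cells,
#' so the high-risk cell fraction is free to differ from
#' 100 - cutoff%).
#'
#' @param model a `risk_model`.
#' @param cells genes x cells expression matrix on the scale used in
#'   training (use log2(TPM+1) for TPM input; see `log_transform`).
#' @param reference the training `survival_cohort` (for the batch
#'   reference).
#' @param log_transform apply log2(TPM+1) to `cells` first (default
#'   TRUE, for TPM input).
#' @return the [normalize_and_classify()] data.frame for the cells.
#' @export
score_cells <- function(model, cells, reference, log_transform = TRUE) {
  stopifnot(inherits(model, "risk_model"))
  x <- if (log_transform) log2p1(cells) else cells
  adj <- batch_adjust(reference$expression[model$genes, , drop = FALSE],
                      x[model$genes, , drop = FALSE])
  offset <- unname(stats::quantile(compute_risk_scores(adj$a, model),
                                   model$cutoff_percentile / 100, type = 7))
  normalize_and_classify(compute_risk_scores(adj$b, model),
                         model$cutoff_percentile, offset_source = offset)
}

#' Serialize a risk model to TSV with a YAML header
#'
#' @param model a `risk_model`.
#' @param path output file.
#' @export
write_risk_model <- function(model, path) {
  stopifnot(inherits(model, "risk_model"))
  hdr <- yaml::as.yaml(list(cutoff_percentile = model$cutoff_percentile,
                            offset = unname(model$offset)),
                       precision = 15L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", strsplit(hdr, "\n")[[1]]), con)
  utils::write.table(
    data.frame(gene = model$genes, beta = unname(model$beta),
               p = unname(model$p)),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a risk model written by [write_risk_model()]
#' @param path file path.
#' @return a `risk_model` (without training scores).
#' @export
read_risk_model <- function(path) {
  ln <- readLines(path)
  hdr <- yaml::yaml.load(paste(sub("^# ?", "", ln[startsWith(ln, "#")]),
                               collapse = "\n"))
  tab <- utils::read.delim(text = ln[!startsWith(ln, "#")])
  model <- list(genes = tab$gene,
                beta = stats::setNames(tab$beta, tab$gene),
                se = NULL,
                p = stats::setNames(tab$p, tab$gene),
                ordering = tab$gene[order(tab$p)],
                converged = NULL,
                cutoff_percentile = hdr$cutoff_percentile,
                offset = hdr$offset)
  class(model) <- "risk_model"
  model
}
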