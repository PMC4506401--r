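#' Call per-cell expressed genotypes from allele read counts
#'
#' Trinary genotyping of each variant in each cell from the RNA read
#' counts at the variant position: `NO_CALL` when total coverage is
#' below `min_depth` (insufficient reads for an unambiguous call),
#' otherwise `MUT_EXPRESSED` when at least `min_alt` mutant reads are
#' seen and the mutant fraction reaches `min_alt_frac`, else
#' `WT_EXPRESSED`.
#'
#' @param ref_depth,alt_depth variants x cells matrices of reference and
#'   mutant read counts (shared dimnames).
#' @param min_depth minimum ref+alt coverage for any call (default 3).
#' @param min_alt minimum mutant reads for a mutant call (default 2).
#' @param min_alt_frac minimum mutant read fraction (default 0.1).
#' @return object of class `cell_genotype_matrix`: list with `calls`
#'   (character matrix in MUT_EXPRESSED/WT_EXPRESSED/NO_CALL), `ref`,
#'   `alt`.
#' @examples
#' ref <- matrix(c(0, 20), 1, 2, dimnames = list("v1", c("a", "b")))
#' alt <- matrix(c(50, 1), 1, 2, dimnames = list("v1", c("a", "b")))
#' call_cell_genotypes(ref, alt)$calls
#' @export
call_cell_genotypes <- function(ref_depth, alt_depth, min_depth = 3L,
                                min_alt = 2L, min_alt_frac = 0.1) {
  if (!identical(dim(ref_depth), dim(alt_depth)))
    stop_invalid("ref_depth and alt_depth must have identical shape")
  if (any(ref_depth < 0) || any(alt_depth < 0))
    stop_invalid("read depths must be nonnegative")
  tot <- ref_depth + alt_depth
  frac <- ifelse(tot > 0, alt_depth / tot, 0)
  calls <- ifelse(tot < min_depth, "NO_CALL",
                  ifelse(alt_depth >= min_alt & frac >= min_alt_frac,
                         "MUT_EXPRESSED", "WT_EXPRESSED"))
  dimnames(calls) <- dimnames(ref_depth)
  out <- list(calls = calls, ref = ref_depth, alt = alt_depth)
  class(out) <- "cell_genotype_matrix"
  out
}

#' @export
print.cell_genotype_matrix <- function(x, ...) {
  cat(sprintf("Cell genotype matrix: %d variants x %d cells\n",
              nrow(x$calls), ncol(x$calls)))
  print(table(x$calls))
  invisible(x)
}

#' Keep variants recurrently mutant across cells
#'
#' Retains variants with `MUT_EXPRESSED` calls in at least `min_cells`
#' cells — the "found in more than three single cells" recurrence rule
#' under the default of 4.
#'
#' @param genotypes a `cell_genotype_matrix`.
#' @param min_cells minimum mutant-cell count (default 4).
#' @return filtered `cell_genotype_matrix`.
#' @export
recurrence_filter <- function(genotypes, min_cells = 4L) {
  stopifnot(inherits(genotypes, "cell_genotype_matrix"))
  nmut <- rowSums(genotypes$calls == "MUT_EXPRESSED")
  keep <- nmut >= min_cells
  out <- list(calls = genotypes$calls[keep, , drop = FALSE],
              ref = genotypes$ref[keep, , drop = FALSE],
              alt = genotypes$alt[keep, , drop = FALSE])
  class(out) <- "cell_genotype_matrix"
  out
}

#' Mutation fraction per variant over total cells
#'
#' Fraction of all cells (NO_CALL cells included in the denominator,
#' matching normalization over total single cells) with a mutant call.
#'
#' @param genotypes a `cell_genotype_matrix` or call matrix.
#' @return named numeric vector in \[0, 1\].
#' @examples
#' # 27 mutant cells of 34 -> 0.794
#' m <- matrix(rep(c("MUT_EXPRESSED", "WT_EXPRESSED"), c(27, 7)), 1, 34,
#'             dimnames = list("KRAS_G12D", NULL))
#' round(mutation_fraction(m), 3)
#' @export
mutation_fraction <- function(genotypes) {
  calls <- if (inherits(genotypes, "cell_genotype_matrix"))
    genotypes$calls else genotypes
  if (ncol(calls) == 0) stop_invalid("zero cells: mutation fraction undefined")
  rowSums(calls == "MUT_EXPRESSED") / ncol(calls)
}

#' Concordance between two genotype call matrices
#'
#' Per-variant and overall agreement between two call sets on shared
#' variants and cells (e.g. RNA-seq versus genotyping PCR). Under
#' `policy = "drop_nocall"` a pair with NO_CALL on either side is
#' excluded from both numerator and denominator; under
#' `"count_nocall"` such pairs count as discordant unless both sides are
#' NO_CALL.
#'
#' @param calls_a,calls_b `cell_genotype_matrix` objects or call
#'   matrices with overlapping dimnames.
#' @param policy NO_CALL handling.
#' @return list with `overall` (fraction), `n_agree`, `n_compared`, and
#'   `per_variant` data.frame; `overall` is NA (flagged) when no pair is
#'   comparable.
#' @export
genotype_concordance <- function(calls_a, calls_b,
                                 policy = c("drop_nocall", "count_nocall")) {
  policy <- match.arg(policy)
  a <- if (inherits(calls_a, "cell_genotype_matrix")) calls_a$calls else calls_a
  b <- if (inherits(calls_b, "cell_genotype_matrix")) calls_b$calls else calls_b
  vars <- intersect(rownames(a), rownames(b))
  cells <- intersect(colnames(a), colnames(b))
  if (length(vars) == 0 || length(cells) == 0)
    stop_invalid("call matrices share no variants/cells")
  a <- a[vars, cells, drop = FALSE]
  b <- b[vars, cells, drop = FALSE]

  if (policy == "drop_nocall") {
    comparable <- a != "NO_CALL" & b != "NO_CALL"
    agree <- comparable & a == b
  } else {
    comparable <- matrix(TRUE, nrow(a), ncol(a))
    agree <- a == b
  }
  per_variant <- data.frame(
    variant = vars,
    n_agree = rowSums(agree),
    n_compared = rowSums(comparable))
  per_variant$concordance <- ifelse(per_variant$n_compared > 0,
                                    per_variant$n_agree / per_variant$n_compared,
                                    NA_real_)
  n_comp <- sum(comparable)
  list(overall = if (n_comp == 0) NA_real_ else sum(agree) / n_comp,
       n_agree = sum(agree), n_compared = n_comp,
       per_variant = per_variant)
}
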