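#' Assign cells to the four genotype-by-risk subgroups
#'
#' Deterministic 2x2 assignment from the two supervised axes:
#' G1 = WT/low risk, G2 = mutant/low, G3 = WT/high, G4 = mutant/high.
#' Cells with a NO_CALL driver genotype are either treated as WT
#' (`nocall_policy = "as_wt"`, flagged) or excluded
#' (`nocall_policy = "exclude"`).
#'
#' @param driver_calls per-cell driver genotype in
#'   MUT_EXPRESSED/WT_EXPRESSED/NO_CALL (named by cell).
#' @param risk_labels per-cell "HIGH"/"LOW" (same order/names).
#' @param nocall_policy NO_CALL handling.
#' @return data.frame of class `subgroup_assignment`: `cell`,
#'   `driver_call`, `risk_label`, `group` (G1..G4, NA when excluded),
#'   `nocall_flag`.
#' @examples
#' assign_subgroups(c(a = "MUT_EXPRESSED", b = "WT_EXPRESSED"),
#'                  c(a = "HIGH", b = "LOW"))
#' @export
assign_subgroups <- function(driver_calls, risk_labels,
                             nocall_policy = c("as_wt", "exclude")) {
  nocall_policy <- match.arg(nocall_policy)
  if (length(driver_calls) != length(risk_labels))
    stop_invalid("driver_calls and risk_labels must align")
  if (!all(risk_labels %in% c("HIGH", "LOW")))
    stop_invalid("risk_labels must be HIGH/LOW")
  ok_calls <- c("MUT_EXPRESSED", "WT_EXPRESSED", "NO_CALL")
  if (!all(driver_calls %in% ok_calls))
    stop_invalid("driver_calls must be in %s", paste(ok_calls, collapse = "/"))

  nocall <- driver_calls == "NO_CALL"
  eff <- ifelse(nocall & nocall_policy == "as_wt", "WT_EXPRESSED",
                driver_calls)
  mut <- eff == "MUT_EXPRESSED"
  high <- risk_labels == "HIGH"
  group <- ifelse(mut & high, "G4",
           ifelse(mut & !high, "G2",
           ifelse(!mut & high, "G3", "G1")))
  group[nocall & nocall_policy == "exclude"] <- NA_character_

  cells <- if (is.null(names(driver_calls))) seq_along(driver_calls)
           else names(driver_calls)
  out <- data.frame(cell = cells, driver_call = unname(driver_calls),
                    risk_label = unname(risk_labels),
                    group = unname(group), nocall_flag = unname(nocall),
                    stringsAsFactors = FALSE)
  class(out) <- c("subgroup_assignment", "data.frame")
  out
}

#' Genes discriminating each subgroup from the rest
#'
#' One-vs-rest selection per group: a gene is selected when the
#' mean-TPM ratio (pseudocount 1 on both means, either direction)
#' reaches `fold` and a two-sided equal-variance Student's t-test on
#' log2(TPM+1) gives p < `alpha`. Pairwise contrasts are available via
#' `contrast = "pairwise"`.
#'
#' @param expr genes x cells TPM matrix.
#' @param groups per-cell group labels (aligned with columns).
#' @param fold minimum fold change (default 2).
#' @param alpha t-test significance threshold (default 0.05).
#' @param contrast "one_vs_rest" (default) or "pairwise".
#' @return data.frame `gene`, `group` (or `group_a`/`group_b` for
#'   pairwise), `fold` (ratio in the selected direction), `p`; groups
#'   with fewer than 2 cells are skipped with a warning.
#' @export
select_discriminating_genes <- function(expr, groups, fold = 2,
                                        alpha = 0.05,
                                        contrast = c("one_vs_rest",
                                                     "pairwise")) {
  contrast <- match.arg(contrast)
  check_expression_matrix(expr)
  if (length(groups) != ncol(expr))
    stop_invalid("one group label per cell required")
  lx <- log2p1(expr)

  test_split <- function(in_idx, out_idx, label) {
    m_in <- rowMeans(expr[, in_idx, drop = FALSE]) + 1
    m_out <- rowMeans(expr[, out_idx, drop = FALSE]) + 1
    ratio <- pmax(m_in / m_out, m_out / m_in)
    cand <- which(ratio >= fold)
    if (length(cand) == 0)
      return(NULL)
    p <- vapply(cand, function(g)
      stats::t.test(lx[g, in_idx], lx[g, out_idx],
                    var.equal = TRUE)$p.value, numeric(1))
    sel <- p < alpha
    if (!any(sel)) return(NULL)
    data.frame(gene = rownames(expr)[cand[sel]], group = label,
               fold = ratio[cand[sel]], p = p[sel],
               stringsAsFactors = FALSE, row.names = NULL)
  }

  lv <- sort(unique(groups[!is.na(groups)]))
  res <- list()
  if (contrast == "one_vs_rest") {
    for (g in lv) {
      in_idx <- which(groups == g)
      out_idx <- which(groups != g & !is.na(groups))
      if (length(in_idx) < 2 || length(out_idx) < 2) {
        warning(sprintf("group %s has <2 cells on one side; skipped", g))
        next
      }
      res[[g]] <- test_split(in_idx, out_idx, g)
    }
  } else {
    for (i in seq_along(lv)) for (j in seq_along(lv)) {
      if (i >= j) next
      a <- which(groups == lv[i]); b <- which(groups == lv[j])
      if (length(a) < 2 || length(b) < 2) {
        warning(sprintf("pair %s/%s skipped (<2 cells)", lv[i], lv[j]))
        next
      }
      r <- test_split(a, b, paste(lv[i], lv[j], sep = "_vs_"))
      res[[paste(lv[i], lv[j])]] <- r
    }
  }
  out <- do.call(rbind, Filter(Negate(is.null), res))
  if (is.null(out))
    out <- data.frame(gene = character(), group = character(),
                      fold = numeric(), p = numeric())
  rownames(out) <- NULL
  out
}

#' Two-sample comparison of a per-cell quantity between groups
#'
#' Two-sided equal-variance Student's t-test between two named groups.
#' When both groups are constant with equal means the test is
#' degenerate; p = 1 is returned with a flag.
#'
#' @param values numeric per-cell values.
#' @param groups per-cell group labels.
#' @param pair length-2 character vector naming the groups to compare.
#' @return list with `t`, `p`, `df`, `mean_a`, `mean_b`, `degenerate`.
#' @export
compare_groups <- function(values, groups, pair) {
  if (length(pair) != 2) stop_invalid("'pair' must name two groups")
  a <- values[groups == pair[1]]
  b <- values[groups == pair[2]]
  if (length(a) < 2 || length(b) < 2)
    stop_invalid("both groups need at least 2 cells")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, p = 1, df = length(a) + length(b) - 2,
                  mean_a = mean(a), mean_b = mean(b), degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_a = mean(a), mean_b = mean(b),
       degenerate = FALSE)
}
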