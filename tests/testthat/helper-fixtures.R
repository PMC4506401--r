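# Shared fixtures, built in code.

# scaled-down configuration for fast end-to-end tests
small_config <- function(seed = 1L, ...) {
  sim_config(n_cells = 40L, n_genes = 400L, n_risk_genes = 20L,
             n_zero_markers = 10L, n_variants = 20L, n_synonymous = 5L,
             n_germline = 8L, cohort_n = 120L, seed = seed, ...)
}

# minimal calls data.frame for filter tests
toy_calls <- function(pos, qual = 50, fs = 5, qd = 10,
                      effect = "non_synonymous", contig = "chrS") {
  k <- length(pos)
  data.frame(id = sprintf("V%02d", seq_len(k)), contig = contig,
             pos = as.integer(pos),
             ref = rep_len("A", k), alt = rep_len("T", k),
             qual = rep_len(qual, k), fs = rep_len(fs, k),
             qd = rep_len(qd, k), effect = rep_len(effect, k),
             ref_depth = rep_len(10L, k), alt_depth = rep_len(5L, k),
             stringsAsFactors = FALSE)
}

# small genotype call matrix from a 0/1 mutation pattern
toy_genotypes <- function(pattern) {
  calls <- ifelse(is.na(pattern), "NO_CALL",
                  ifelse(pattern == 1, "MUT_EXPRESSED", "WT_EXPRESSED"))
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("v%02d", seq_len(nrow(calls)))
  if (is.null(colnames(calls)))
    colnames(calls) <- sprintf("c%02d", seq_len(ncol(calls)))
  calls
}

# six-subject survival toys for the Cox oracle suite
cox_fixtures <- function() {
  list(
    list(x = c(0.5, -1.2, 0.3, 2.0, -0.7, 1.1),
         time = c(2, 5, 1, 8, 3, 6), event = c(1, 1, 1, 0, 1, 1)),
    list(x = c(1, 0, 1, 0, 1, 0),
         time = c(1, 2, 3, 4, 5, 6), event = c(1, 1, 0, 1, 1, 1)),
    list(x = c(-2, -1, 0, 1, 2, 3),
         time = c(4, 4, 2, 7, 2, 9), event = c(1, 0, 1, 1, 1, 1)),
    list(x = c(0.1, 0.9, -0.4, 1.5, -1.1, 0.6, 0.2, -0.8),
         time = c(3, 3, 5, 1, 6, 2, 7, 4), event = c(1, 1, 1, 1, 0, 1, 1, 1))
  )
}
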