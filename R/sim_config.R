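#' Simulation configuration for the synthetic tumor population
#'
#' Builds the parameter object consumed by every generator in the package.
#' The defaults describe a lung-adenocarcinoma-like PDX single-cell
#' population: four subclonal groups laid out on a 2x2 design of
#' driver-mutant allele expression (groups G2/G4) by an activated
#' prognostic risk program (groups G3/G4), with group sizes proportional
#' to 3/25/3/35, a 69-gene risk program, a highly expressed driver
#' oncogene, and allelic dropout concentrated in low-coverage transcripts.
#'
#' @param n_cells number of single cells.
#' @param group_fractions length-4 nonnegative vector summing to 1; the
#'   expected fractions of groups G1 (WT/low-risk), G2 (MUT/low),
#'   G3 (WT/high), G4 (MUT/high).
#' @param n_genes size of the gene universe (includes the driver gene,
#'   the risk program and the always-zero marker decoys).
#' @param n_risk_genes number of risk-program genes.
#' @param risk_effect log2-fold shift of risk-program genes in the
#'   high-risk groups G3/G4.
#' @param driver_expr_level mean TPM of the driver gene (driver mutations
#'   are genotypable from RNA only when the host transcript is abundant).
#' @param mutant_allele_fraction length-4 vector: per-group probability
#'   that a cell carries (and expresses) the driver-mutant allele. The
#'   default `c(0, 1, 0, 1)` makes group membership synonymous with
#'   mutant-allele expression, so RNA-level non-detection is attributable
#'   to read-level dropout alone.
#' @param depth_mean mean read depth at a variant site whose host gene is
#'   at the average expression level; per-cell depths scale with the host
#'   gene's TPM.
#' @param dropout_scale,dropout_d0 allelic dropout probability at depth d
#'   is `dropout_scale * exp(-d / dropout_d0)`: depth-dependent, so
#'   mutations on rare transcripts are the most dropout-prone.
#' @param n_variants number of somatic non-synonymous variants (the
#'   tumor-specific set the pipeline should recover).
#' @param n_synonymous number of somatic synonymous variants.
#' @param n_germline number of germline variants (present in the matched
#'   normal exome).
#' @param n_artifacts named integer vector `c(editing, cluster,
#'   low_quality)`: planted RNA-seq artifact calls — editing/repeat
#'   blacklist sites, clusters of 3 variants within the cluster window,
#'   and records failing the Q/FS/QD annotations.
#' @param cohort_n training-cohort size for the survival generator.
#' @param cohort_beta per-gene log-hazard coefficient planted on each
#'   risk-program gene in the survival cohort.
#' @param baseline_hazard event rate per unit time at covariate center.
#' @param censor_rate rate of the independent exponential censoring
#'   process (0 = administrative follow-up only, no censoring).
#' @param n_zero_markers marker-panel decoy genes with zero expression in
#'   every single cell (they are expressed in the patient cohort).
#' @param expr_sd per-cell log2 expression noise SD.
#' @param cell_size_sd SD of the per-cell log2 size factor.
#' @param contig,contig_length name and length of the toy contig on which
#'   variants are placed.
#' @param seed integer RNG seed; identical seeds give bit-identical
#'   outputs from every generator.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_cells = 40, seed = 7)
#' cfg$group_fractions
#' @export
sim_config <- function(n_cells = 66L,
                       group_fractions = c(3, 25, 3, 35) / 66,
                       n_genes = 2000L,
                       n_risk_genes = 69L,
                       risk_effect = 1.0,
                       driver_expr_level = 3000,
                       mutant_allele_fraction = c(0, 1, 0, 1),
                       depth_mean = 30,
                       dropout_scale = 1.0,
                       dropout_d0 = 10,
                       n_variants = 50L,
                       n_synonymous = 15L,
                       n_germline = 20L,
                       n_artifacts = c(editing = 4L, cluster = 2L, low_quality = 6L),
                       cohort_n = 200L,
                       cohort_beta = 0.3,
                       baseline_hazard = 0.1,
                       censor_rate = 0.05,
                       n_zero_markers = 31L,
                       expr_sd = 1.0,
                       cell_size_sd = 0.2,
                       contig = "chrS",
                       contig_length = 1e6,
                       seed = 1L) {
  n_cells <- check_count(n_cells, "n_cells")
  n_genes <- check_count(n_genes, "n_genes", min = 1L)
  n_risk_genes <- check_count(n_risk_genes, "n_risk_genes")
  n_variants <- check_count(n_variants, "n_variants")
  n_synonymous <- check_count(n_synonymous, "n_synonymous")
  n_germline <- check_count(n_germline, "n_germline")
  n_zero_markers <- check_count(n_zero_markers, "n_zero_markers")
  cohort_n <- check_count(cohort_n, "cohort_n")

  if (length(group_fractions) != 4L || any(group_fractions < 0))
    stop_invalid("'group_fractions' must be 4 nonnegative values")
  if (abs(sum(group_fractions) - 1) > 1e-9)
    stop_invalid("'group_fractions' must sum to 1 (got %.12g)", sum(group_fractions))
  if (length(mutant_allele_fraction) != 4L)
    stop_invalid("'mutant_allele_fraction' must have length 4")
  check_prob(mutant_allele_fraction, "mutant_allele_fraction")
  check_prob(dropout_scale, "dropout_scale")
  if (baseline_hazard <= 0)
    stop_invalid("'baseline_hazard' must be positive")
  if (censor_rate < 0)
    stop_invalid("'censor_rate' must be nonnegative")
  if (dropout_d0 <= 0)
    stop_invalid("'dropout_d0' must be positive")
  needed <- c("editing", "cluster", "low_quality")
  if (!all(needed %in% names(n_artifacts)))
    stop_invalid("'n_artifacts' needs named entries: %s",
                 paste(needed, collapse = ", "))
  n_artifacts <- vapply(needed, function(k) check_count(n_artifacts[[k]], k),
                        integer(1))
  if (n_genes < n_risk_genes + n_zero_markers + 1L)
    stop_invalid("'n_genes' must exceed n_risk_genes + n_zero_markers + 1 (driver)")

  cfg <- list(
    n_cells = n_cells, group_fractions = as.numeric(group_fractions),
    n_genes = n_genes, n_risk_genes = n_risk_genes,
    risk_effect = risk_effect, driver_expr_level = driver_expr_level,
    mutant_allele_fraction = as.numeric(mutant_allele_fraction),
    depth_mean = depth_mean, dropout_scale = dropout_scale,
    dropout_d0 = dropout_d0,
    n_variants = n_variants, n_synonymous = n_synonymous,
    n_germline = n_germline, n_artifacts = n_artifacts,
    cohort_n = cohort_n, cohort_beta = cohort_beta,
    baseline_hazard = baseline_hazard, censor_rate = censor_rate,
    n_zero_markers = n_zero_markers, expr_sd = expr_sd,
    cell_size_sd = cell_size_sd, contig = contig,
    contig_length = contig_length, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Allelic dropout probability at a given read depth
#'
#' @param d read depth (vectorized).
#' @param config a [sim_config()].
#' @return dropout probabilities `dropout_scale * exp(-d / dropout_d0)`.
#' @export
dropout_rate <- function(d, config) {
  config$dropout_scale * exp(-d / config$dropout_d0)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic tumor population configuration\n")
  cat(sprintf("  cells: %d in groups G1..G4 = %s\n", x$n_cells,
              paste(signif(x$group_fractions, 3), collapse = "/")))
  cat(sprintf("  genes: %d (%d risk-program, %d zero-marker decoys, 1 driver)\n",
              x$n_genes, x$n_risk_genes, x$n_zero_markers))
  cat(sprintf("  variants: %d somatic non-syn, %d syn, %d germline; artifacts %s\n",
              x$n_variants, x$n_synonymous, x$n_germline,
              paste(sprintf("%s=%d", names(x$n_artifacts), x$n_artifacts),
                    collapse = " ")))
  cat(sprintf("  dropout(d) = %.2f * exp(-d/%.1f); depth_mean = %.1f\n",
              x$dropout_scale, x$dropout_d0, x$depth_mean))
  cat(sprintf("  cohort: n=%d, beta=%.2f per risk gene, h0=%.3f, censor=%.3f\n",
              x$cohort_n, x$cohort_beta, x$baseline_hazard, x$censor_rate))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Serialize a configuration to YAML
#'
#' @param config a [sim_config()].
#' @param path optional file; when `NULL` the YAML string is returned.
#' @return the YAML string, invisibly when written to file.
#' @export
config_yaml <- function(config, path = NULL) {
  stopifnot(inherits(config, "sim_config"))
  y <- yaml::as.yaml(lapply(unclass(config), function(v)
    if (is.numeric(v)) unname(v) else v), precision = 15L)
  if (is.null(path)) return(y)
  writeLines(y, path)
  invisible(y)
}

# Deterministic gene-universe metadata shared by the cell-population and
# survival-cohort generators: names, baseline log2 abundances, and the
# roles (driver / risk program / always-zero marker decoys).
gene_model <- function(config) {
  set.seed(config$seed)
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  mu <- stats::rnorm(config$n_genes, mean = 3, sd = 1.5)
  names(mu) <- genes
  roles <- rep("background", config$n_genes)
  idx <- seq_len(config$n_genes)
  driver <- 1L
  risk <- seq.int(2L, length.out = config$n_risk_genes)
  zero <- seq.int(2L + config$n_risk_genes, length.out = config$n_zero_markers)
  roles[driver] <- "driver"
  roles[risk] <- "risk"
  roles[zero] <- "zero_marker"
  mu[driver] <- log2(config$driver_expr_level)
  list(genes = genes, mu = mu, roles = roles,
       driver_gene = genes[driver], risk_genes = genes[risk],
       zero_markers = genes[zero],
       marker_panel = c(genes[risk], genes[zero]))
}
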