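#' Generate a synthetic single-cell tumor population
#'
#' Plants four subclonal groups on a 2x2 design: the risk-program genes
#' are shifted up by `risk_effect` (log2 units) in the high-risk groups
#' G3/G4, and the driver-mutant allele is carried (and expressed) by
#' cells of the mutant groups G2/G4 with probability
#' `mutant_allele_fraction`. Expression is log-normal TPM with a per-cell
#' size factor; somatic-variant read depths are Poisson with mean
#' proportional to the host gene's TPM; mutant-allele reads are binomial
#' with depth-dependent allelic-dropout zero inflation
#' (`dropout_scale * exp(-depth/dropout_d0)`).
#'
#' @param config a [sim_config()]; `n_cells >= 4` and at least one
#'   positive group fraction are required.
#' @return A list of class `sc_population`:
#' \describe{
#'   \item{expr}{genes x cells TPM matrix (columns sum to 1e6; values
#'     below 1 TPM truncated to 0).}
#'   \item{reads}{list with `ref` and `alt` (variants x cells depth
#'     matrices), `variant_gene` (host gene per variant) and
#'     `driver_variant` (the flagged driver variant id).}
#'   \item{truth}{ground truth: `cell_group` (G1..G4 per cell),
#'     `dna_genotype` (variants x cells, het/hom/absent),
#'     `surviving_group_per_drug` (filled by [generate_drug_treatment()]).
#'     Truth is emitted for benchmarking and must never feed an analysis
#'     stage.}
#' }
#' @examples
#' pop <- generate_cell_population(sim_config(n_cells = 12, seed = 5))
#' table(pop$truth$cell_group)
#' @export
generate_cell_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_cells < 4L)
    stop_invalid("'n_cells' must be at least 4")
  if (abs(sum(config$group_fractions) - 1) > 1e-9)
    stop_invalid("'group_fractions' must sum to 1")

  gm <- gene_model(config)
  set.seed(config$seed + 2002L)
  n <- config$n_cells
  cells <- sprintf("C%03d", seq_len(n))
  groups <- paste0("G", sample.int(4L, n, replace = TRUE,
                                   prob = config$group_fractions))
  names(groups) <- cells
  high_risk <- groups %in% c("G3", "G4")
  mutant_grp <- groups %in% c("G2", "G4")

  # log2 expression: gene baseline + group shift + cell size factor + noise
  size <- stats::rnorm(n, 0, config$cell_size_sd)
  lx <- matrix(stats::rnorm(config$n_genes * n, 0, config$expr_sd),
               nrow = config$n_genes, ncol = n,
               dimnames = list(gm$genes, cells))
  lx <- lx + gm$mu + rep(size, each = config$n_genes)
  lx[gm$risk_genes, high_risk] <- lx[gm$risk_genes, high_risk] + config$risk_effect
  tpm <- 2^lx
  tpm[gm$zero_markers, ] <- 0
  tpm[tpm < 1] <- 0
  tpm <- renorm_tpm(tpm)

  # somatic variant set: the driver plus random-genotype passengers
  n_som <- config$n_variants
  variants <- sprintf("SOM%03d", seq_len(max(n_som, 1L)))
  host_pool <- setdiff(gm$genes, c(gm$zero_markers, gm$driver_gene))
  variant_gene <- sample(host_pool, n_som, replace = n_som > length(host_pool))
  driver_variant <- variants[1L]
  variant_gene[1L] <- gm$driver_gene
  names(variant_gene) <- variants

  # true DNA genotypes: driver follows the planted 2x2 design; passenger
  # prevalences vary to mimic heterogeneous subclonal mutation patterns
  geno <- matrix("absent", nrow = n_som, ncol = n,
                 dimnames = list(variants, cells))
  maf <- config$mutant_allele_fraction[as.integer(sub("G", "", groups))]
  has_driver <- stats::runif(n) < maf
  geno[driver_variant, has_driver] <- "het"
  if (n_som > 1L) {
    prev <- stats::runif(n_som - 1L, 0.2, 0.8)
    for (v in 2:n_som) {
      carrier <- stats::runif(n) < prev[v - 1L]
      zyg <- ifelse(stats::runif(n) < 0.1, "hom", "het")
      geno[v, carrier] <- zyg[carrier]
    }
  }

  # read counts: depth ~ Poisson(depth_mean * TPM_host / mean TPM),
  # mutant reads binomial(depth, 0.5 | 1) with dropout zero-inflation
  mean_tpm <- 1e6 / config$n_genes
  depth_lambda <- config$depth_mean * tpm[variant_gene, , drop = FALSE] / mean_tpm
  depth <- matrix(stats::rpois(n_som * n, depth_lambda), nrow = n_som,
                  dimnames = list(variants, cells))
  p_alt <- matrix(0, n_som, n)
  p_alt[geno == "het"] <- 0.5
  p_alt[geno == "hom"] <- 1
  alt <- matrix(stats::rbinom(n_som * n, depth, p_alt), nrow = n_som,
                dimnames = list(variants, cells))
  drop_mask <- matrix(stats::runif(n_som * n) < dropout_rate(depth, config),
                      nrow = n_som)
  alt[drop_mask & geno != "absent"] <- 0L
  ref <- depth - alt

  truth <- list(cell_group = groups, dna_genotype = geno,
                surviving_group_per_drug = list())
  out <- list(expr = tpm,
              reads = list(ref = ref, alt = alt,
                           variant_gene = variant_gene,
                           driver_variant = driver_variant),
              truth = truth,
              genes = gm)
  class(out) <- "sc_population"
  out
}

#' @export
print.sc_population <- function(x, ...) {
  cat(sprintf("Synthetic single-cell population: %d cells x %d genes, %d somatic variants\n",
              ncol(x$expr), nrow(x$expr), nrow(x$reads$alt)))
  print(table(x$truth$cell_group))
  invisible(x)
}

#' Pool single cells into a synthetic bulk expression profile
#'
#' The bulk is the weighted mean of the cell TPM profiles, re-normalized
#' to 1e6 total, with optional multiplicative log-normal noise.
#'
#' @param cells genes x cells TPM matrix (or an `sc_population`).
#' @param weights nonnegative per-cell weights (default uniform).
#' @param noise_sd SD of the log-normal noise on the natural-log scale.
#' @param seed optional seed for the noise draw.
#' @return named numeric vector of bulk TPM values.
#' @examples
#' pop <- generate_cell_population(sim_config(n_cells = 8, seed = 2))
#' blk <- generate_bulk_profile(pop$expr)
#' sum(blk)
#' @export
generate_bulk_profile <- function(cells, weights = NULL, noise_sd = 0,
                                  seed = NULL) {
  if (inherits(cells, "sc_population")) cells <- cells$expr
  check_expression_matrix(cells, "cells")
  n <- ncol(cells)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n)
    stop_invalid("'weights' must have one entry per cell (%d)", n)
  if (any(weights < 0) || any(!is.finite(weights)))
    stop_invalid("'weights' must be finite and nonnegative")
  if (sum(weights) == 0)
    stop_invalid("all-zero 'weights': the bulk would contain no cells")
  if (noise_sd < 0) stop_invalid("'noise_sd' must be nonnegative")

  bulk <- drop(cells %*% (weights / sum(weights)))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    bulk <- bulk * exp(stats::rnorm(length(bulk), 0, noise_sd))
  }
  bulk <- bulk / sum(bulk) * 1e6
  names(bulk) <- rownames(cells)
  bulk
}

#' Simulate drug treatment by subclone-selective survival
#'
#' Each cell survives a treatment with its group's survival probability;
#' the treated bulk is pooled over survivors. An all-ones efficacy map
#' therefore reproduces the control bulk in distribution.
#'
#' @param cells an `sc_population` from [generate_cell_population()].
#' @param efficacy named numeric vector mapping groups (`G1`..`G4`) to
#'   survival probabilities in \[0, 1\].
#' @param seed RNG seed for the survival draws.
#' @param drug label used to record the surviving group in the truth map.
#' @param noise_sd passed to [generate_bulk_profile()].
#' @return list with `bulk` (treated-bulk TPM vector), `survivors`
#'   (cell ids), and `truth` (the population truth with
#'   `surviving_group_per_drug[[drug]]` filled with the modal surviving
#'   group).
#' @export
generate_drug_treatment <- function(cells, efficacy, seed = 1L,
                                    drug = "drug", noise_sd = 0) {
  stopifnot(inherits(cells, "sc_population"))
  groups <- cells$truth$cell_group
  if (!all(unique(groups) %in% names(efficacy)))
    stop_invalid("'efficacy' must name every group present in the population")
  check_prob(unlist(efficacy), "efficacy")

  set.seed(seed)
  p <- unlist(efficacy)[groups]
  alive <- stats::runif(length(groups)) < p
  if (!any(alive))
    stop_invalid("no cells survived treatment '%s': empty-survivor condition", drug)
  survivors <- names(groups)[alive]
  bulk <- generate_bulk_profile(cells$expr[, survivors, drop = FALSE],
                                noise_sd = noise_sd, seed = seed + 1L)
  truth <- cells$truth
  tab <- table(groups[alive])
  truth$surviving_group_per_drug[[drug]] <- names(tab)[which.max(tab)]
  list(bulk = bulk, survivors = survivors, truth = truth)
}
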