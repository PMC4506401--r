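# End-to-end convenience wrappers tying the stages together the way the
# analysis is meant to be run; used by the examples, the benchmark
# script and the test-bench.

#' Assign synthetic cells to subgroups with the full analysis path
#'
#' Trains the risk model on the survival cohort (marker panel filtered
#' against the cells), scores the cells with the training-derived
#' offset after batch adjustment, genotypes the driver variant from the
#' cells' allele read counts, and applies the deterministic 2x2
#' subgroup assignment. Only data products are consumed — never the
#' generator's ground truth.
#'
#' @param pop an `sc_population`.
#' @param cohort a `survival_cohort` from the same [sim_config()].
#' @param nocall_policy NO_CALL handling for the driver genotype.
#' @param min_depth,min_alt,min_alt_frac genotype-call thresholds.
#' @return list with `assignment` (a `subgroup_assignment`), `model`
#'   (the `risk_model`), `risk` (per-cell normalized scores/labels) and
#'   `genotypes` (the `cell_genotype_matrix`).
#' @export
recover_subgroups <- function(pop, cohort, nocall_policy = "as_wt",
                              min_depth = 3L, min_alt = 2L,
                              min_alt_frac = 0.1) {
  stopifnot(inherits(pop, "sc_population"),
            inherits(cohort, "survival_cohort"))
  model <- train_risk_model(cohort, markers = pop$genes$marker_panel,
                            cells = pop$expr)
  risk <- score_cells(model, pop$expr, cohort)
  geno <- call_cell_genotypes(pop$reads$ref, pop$reads$alt,
                              min_depth = min_depth, min_alt = min_alt,
                              min_alt_frac = min_alt_frac)
  driver <- geno$calls[pop$reads$driver_variant, ]
  labels <- stats::setNames(risk$label, risk$sample)[names(driver)]
  assignment <- assign_subgroups(driver, labels,
                                 nocall_policy = nocall_policy)
  list(assignment = assignment, model = model, risk = risk,
       genotypes = geno)
}

#' Adjusted Rand index between an assignment and reference labels
#'
#' @param assigned,reference label vectors (NAs dropped pairwise).
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(assigned, reference) {
  ok <- !is.na(assigned) & !is.na(reference)
  mclust::adjustedRandIndex(assigned[ok], reference[ok])
}

#' One full synthetic subgroup-recovery run
#'
#' Generates a population and cohort from `config`, recovers subgroups
#' with [recover_subgroups()], and reports the adjusted Rand index
#' against the planted groups (truth used only for this final
#' benchmark comparison).
#'
#' @param config a [sim_config()].
#' @return list with `ari`, `assignment`, `pop`, `cohort`, `model`.
#' @export
subgroup_recovery_run <- function(config = sim_config()) {
  pop <- generate_cell_population(config)
  cohort <- generate_survival_cohort(config)
  rec <- recover_subgroups(pop, cohort)
  ari <- adjusted_rand_index(rec$assignment$group,
                             pop$truth$cell_group[rec$assignment$cell])
  list(ari = ari, assignment = rec$assignment, pop = pop,
       cohort = cohort, model = rec$model, risk = rec$risk)
}

#' One full drug-response classification run
#'
#' Builds the complete readout: subgroup assignment, discriminating
#' genes, single-cell PCA, C-SVM classifier, then classifies a control
#' bulk (all cells survive) and a drug-treated bulk in which only one
#' group survives.
#'
#' @param config a [sim_config()].
#' @param surviving_group group selected by the simulated drug
#'   (default "G2", the mutant/low-risk drug-tolerant phenotype).
#' @param n_components PC-space dimensionality for the classifier.
#' @return list with `control_label`, `treated_label`,
#'   `dominant_group` (the group planted as dominant, i.e. the largest
#'   configured group fraction), `drawn_counts` (realized group sizes),
#'   `surviving_group`, `classifier`, `pca`.
#' @export
drug_response_run <- function(config = sim_config(),
                              surviving_group = "G2",
                              n_components = 2L) {
  pop <- generate_cell_population(config)
  cohort <- generate_survival_cohort(config)
  rec <- recover_subgroups(pop, cohort)
  groups <- stats::setNames(rec$assignment$group, rec$assignment$cell)

  disc <- select_discriminating_genes(pop$expr, groups[colnames(pop$expr)])
  genes <- unique(disc$gene)
  if (length(genes) < 2)
    stop_invalid("fewer than 2 discriminating genes; cannot build PC space")
  fit <- pca_expression(pop$expr[genes, , drop = FALSE],
                        pool_groups = groups[colnames(pop$expr)])
  # groups with a single assigned cell cannot anchor an SVM class
  g_train <- groups[rownames(fit$scores)]
  tab <- table(g_train)
  g_train[g_train %in% names(tab)[tab < 2]] <- NA
  clf <- train_group_classifier(fit$scores, g_train,
                                n_components = n_components)

  efficacy_all <- stats::setNames(rep(1, 4), paste0("G", 1:4))
  control <- generate_drug_treatment(pop, efficacy_all,
                                     seed = config$seed + 11L,
                                     drug = "control")
  efficacy_drug <- stats::setNames(as.numeric(paste0("G", 1:4) ==
                                                surviving_group),
                                   paste0("G", 1:4))
  treated <- generate_drug_treatment(pop, efficacy_drug,
                                     seed = config$seed + 12L,
                                     drug = "drug")

  proj <- project_bulk(cbind(control = control$bulk,
                             treated = treated$bulk), fit,
                       n_components = n_components,
                       pool_correction = TRUE)
  cls <- classify_samples(clf, proj)
  list(control_label = cls$group[cls$sample == "control"],
       treated_label = cls$group[cls$sample == "treated"],
       dominant_group = paste0("G", which.max(config$group_fractions)),
       drawn_counts = table(pop$truth$cell_group),
       surviving_group = surviving_group,
       classifier = clf, pca = fit, classified = cls)
}
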