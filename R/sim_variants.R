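#' Generate a synthetic variant call set with planted artifacts
#'
#' Emits the RNA-seq-style variant calls the filter cascade consumes:
#' true somatic variants (the population's non-synonymous set plus
#' synonymous ones), germline variants that also appear in the matched
#' normal exome, and planted artifact calls of three kinds — editing-type
#' sites that land on the site/repeat blacklists, clusters of three
#' variants within the 35-bp cluster window, and records failing the
#' quality annotations (call quality Q < 20, Fisher strand FS > 30 or
#' quality-by-depth QD < 2). True variants are placed at least 100 bp
#' apart so no accidental cluster forms. Matched tumor/normal exome key
#' sets are emitted alongside (artifacts are RNA-only and absent from
#' both).
#'
#' @param truth the `truth` element of an `sc_population` (its somatic
#'   variant ids and DNA genotypes set the bulk allele fractions).
#' @param config the same [sim_config()] used for the population.
#' @return list of class `variant_callset`:
#'   `rna` (data.frame: id, contig, pos, ref, alt, qual, fs, qd, effect,
#'   ref_depth, alt_depth for the tumor bulk sample), `wes_tumor`,
#'   `wes_normal` (key data.frames), `editing_sites` (1-based site list),
#'   `repeats` (0-based half-open BED data.frame), and `plant`
#'   (id -> planted class; benchmarking only).
#' @export
generate_variant_callset <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_variants < 1L)
    stop_invalid("'n_variants' must be at least 1")

  set.seed(config$seed + 3003L)
  geno <- truth$dna_genotype
  som_ids <- rownames(geno)
  n_syn <- config$n_synonymous
  n_gl <- config$n_germline
  na <- config$n_artifacts
  n_single <- length(som_ids) + n_syn + n_gl + na[["editing"]] +
    na[["low_quality"]] + na[["cluster"]]

  grid <- seq(1000L, as.integer(config$contig_length) - 1000L, by = 100L)
  if (n_single > length(grid))
    stop_invalid("contig too short for the requested variant count")
  anchor <- sample(grid, n_single)

  bases <- c("A", "C", "G", "T")
  new_rec <- function(id, pos, qual, fs, qd, effect, vaf) {
    ref <- sample(bases, length(pos), replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
    dp <- stats::rpois(length(pos), 100)
    ad <- stats::rbinom(length(pos), dp, pmin(vaf, 1))
    ad <- pmax(ad, 1L)  # a called variant has at least one supporting read
    data.frame(id = id, contig = config$contig, pos = as.integer(pos),
               ref = ref, alt = alt, qual = qual, fs = fs, qd = qd,
               effect = effect, ref_depth = pmax(dp - ad, 0L),
               alt_depth = ad, stringsAsFactors = FALSE)
  }
  clean_q <- function(k) stats::runif(k, 30, 100)
  clean_fs <- function(k) stats::runif(k, 0, 20)
  clean_qd <- function(k) stats::runif(k, 5, 30)

  take <- function(k) {
    out <- anchor[seq_len(k)]
    anchor <<- anchor[-seq_len(k)]
    out
  }

  # true somatic variants: bulk VAF from the planted cell genotypes
  n_som <- length(som_ids)
  som_vaf <- pmax(0.5 * rowMeans(geno == "het") + rowMeans(geno == "hom"), 0.02)
  rec_som <- new_rec(som_ids, take(n_som), clean_q(n_som), clean_fs(n_som),
                     clean_qd(n_som), "non_synonymous", som_vaf)
  rec_syn <- if (n_syn > 0)
    new_rec(sprintf("SYN%03d", seq_len(n_syn)), take(n_syn), clean_q(n_syn),
            clean_fs(n_syn), clean_qd(n_syn), "synonymous",
            stats::runif(n_syn, 0.2, 0.6))
  rec_gl <- if (n_gl > 0)
    new_rec(sprintf("GL%03d", seq_len(n_gl)), take(n_gl), clean_q(n_gl),
            clean_fs(n_gl), clean_qd(n_gl),
            sample(c("non_synonymous", "synonymous"), n_gl, replace = TRUE),
            rep(0.5, n_gl))

  # editing-type artifacts: odd ones listed as editing sites, even ones
  # covered by a repeat interval, so both blacklist paths are exercised
  n_ed <- na[["editing"]]
  rec_ed <- NULL; editing_sites <- NULL; repeats <- NULL
  if (n_ed > 0) {
    pos_ed <- take(n_ed)
    rec_ed <- new_rec(sprintf("ARTED%02d", seq_len(n_ed)), pos_ed,
                      clean_q(n_ed), clean_fs(n_ed), clean_qd(n_ed),
                      "non_synonymous", stats::runif(n_ed, 0.05, 0.3))
    on_list <- seq_len(n_ed) %% 2L == 1L
    if (any(on_list))
      editing_sites <- data.frame(contig = config$contig,
                                  pos = as.integer(pos_ed[on_list]))
    if (any(!on_list))
      repeats <- data.frame(contig = config$contig,
                            start = as.integer(pos_ed[!on_list] - 10L),
                            end = as.integer(pos_ed[!on_list] + 10L))
  }

  # low-quality artifacts cycle through the three failing annotations
  n_lq <- na[["low_quality"]]
  rec_lq <- NULL
  if (n_lq > 0) {
    mode <- rep_len(c("qual", "fs", "qd"), n_lq)
    q <- clean_q(n_lq); f <- clean_fs(n_lq); d <- clean_qd(n_lq)
    q[mode == "qual"] <- stats::runif(sum(mode == "qual"), 2, 19)
    f[mode == "fs"] <- stats::runif(sum(mode == "fs"), 31, 60)
    d[mode == "qd"] <- stats::runif(sum(mode == "qd"), 0.2, 1.9)
    rec_lq <- new_rec(sprintf("ARTLQ%02d", seq_len(n_lq)), take(n_lq),
                      q, f, d, "non_synonymous", stats::runif(n_lq, 0.05, 0.3))
  }

  # clustered artifacts: 3 variants spanning 30 bp from an anchor
  n_cl <- na[["cluster"]]
  rec_cl <- NULL
  if (n_cl > 0) {
    base <- take(n_cl)
    pos_cl <- as.vector(vapply(base, function(p) p + c(0L, 12L, 30L),
                               integer(3)))
    k <- 3L * n_cl
    rec_cl <- new_rec(sprintf("ARTCL%02d", seq_len(k)), pos_cl,
                      clean_q(k), clean_fs(k), clean_qd(k),
                      "non_synonymous", stats::runif(k, 0.05, 0.3))
  }

  rna <- do.call(rbind, Filter(Negate(is.null),
                               list(rec_som, rec_syn, rec_gl, rec_ed,
                                    rec_lq, rec_cl)))
  rna <- rna[order(rna$contig, rna$pos), , drop = FALSE]
  rownames(rna) <- NULL

  key_cols <- c("id", "contig", "pos", "ref", "alt")
  wes_tumor <- rbind(rec_som[key_cols],
                     if (!is.null(rec_syn)) rec_syn[key_cols],
                     if (!is.null(rec_gl)) rec_gl[key_cols])
  wes_normal <- if (!is.null(rec_gl)) rec_gl[key_cols] else
    wes_tumor[0, ]

  plant <- data.frame(
    id = rna$id,
    class = ifelse(grepl("^SOM", rna$id), "somatic_nonsyn",
            ifelse(grepl("^SYN", rna$id), "somatic_syn",
            ifelse(grepl("^GL", rna$id), "germline",
            ifelse(grepl("^ARTED", rna$id), "artifact_editing",
            ifelse(grepl("^ARTLQ", rna$id), "artifact_lowq",
                   "artifact_cluster"))))),
    stringsAsFactors = FALSE)

  out <- list(rna = rna, wes_tumor = wes_tumor, wes_normal = wes_normal,
              editing_sites = editing_sites, repeats = repeats,
              plant = plant)
  class(out) <- "variant_callset"
  out
}

#' @export
print.variant_callset <- function(x, ...) {
  cat(sprintf("Variant call set: %d RNA records (%d in tumor WES, %d germline)\n",
              nrow(x$rna), nrow(x$wes_tumor), nrow(x$wes_normal)))
  print(table(x$plant$class))
  invisible(x)
}
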