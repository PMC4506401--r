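# Variant filter cascade: RNA-seq calls -> tumor-specific expressed SNVs.
# Each stage only removes records; the cascade order is quality,
# cluster, site annotations (FS/QD), blacklists, WES overlap, somatic
# non-synonymous selection.

variant_key <- function(calls) {
  paste(calls$contig, calls$pos, calls$ref, calls$alt, sep = ":")
}

log_removal <- function(calls, keep, stage) {
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- c(attr(calls, "removed", exact = TRUE),
                            stats::setNames(sum(!keep), stage))
  out
}

#' Remove variant calls below a call-quality threshold
#'
#' @param calls calls data.frame (see [generate_variant_callset()]).
#' @param min_q minimum phred-scaled call quality retained (default 20;
#'   records with `qual >= min_q` pass).
#' @return filtered calls; attribute `removed` accumulates per-stage
#'   removal counts.
#' @export
filter_by_quality <- function(calls, min_q = 20) {
  if (nrow(calls) == 0) return(log_removal(calls, logical(0), "quality"))
  if (is.null(calls$qual)) stop_invalid("calls lack a 'qual' column")
  log_removal(calls, calls$qual >= min_q, "quality")
}

#' Remove clustered variant calls
#'
#' Removes every record that belongs to a run of at least `cluster`
#' variants on one contig whose first-to-last position difference is at
#' most `window` bases (the SNP-cluster convention of GATK
#' VariantFiltration, `-window 35 -cluster 3`).
#'
#' @param calls calls data.frame (sorted internally by contig, pos).
#' @param window cluster window in bases (default 35).
#' @param cluster minimum run length (default 3).
#' @return filtered calls.
#' @export
filter_variant_clusters <- function(calls, window = 35L, cluster = 3L) {
  if (nrow(calls) == 0) return(log_removal(calls, logical(0), "cluster"))
  ord <- order(calls$contig, calls$pos)
  calls_s <- calls[ord, , drop = FALSE]
  attr(calls_s, "removed") <- attr(calls, "removed", exact = TRUE)
  bad <- logical(nrow(calls_s))
  for (ctg in unique(calls_s$contig)) {
    idx <- which(calls_s$contig == ctg)
    pos <- calls_s$pos[idx]
    k <- length(idx)
    if (k < cluster) next
    for (i in seq_len(k - cluster + 1L)) {
      j <- i + cluster - 1L
      if (pos[j] - pos[i] <= window) bad[idx[i:j]] <- TRUE
    }
  }
  log_removal(calls_s, !bad, "cluster")
}

#' Remove calls failing strand-bias / quality-by-depth annotations
#'
#' Removes records with Fisher strand `fs > max_fs` or quality-by-depth
#' `qd < min_qd`. Records lacking the annotations pass with a warning.
#'
#' @param calls calls data.frame.
#' @param max_fs maximum FS retained (default 30.0).
#' @param min_qd minimum QD retained (default 2.0).
#' @return filtered calls.
#' @export
filter_by_site_annotations <- function(calls, max_fs = 30.0, min_qd = 2.0) {
  if (nrow(calls) == 0) return(log_removal(calls, logical(0), "site_annotations"))
  fs <- calls$fs
  qd <- calls$qd
  if (is.null(fs) || is.null(qd) || anyNA(fs) || anyNA(qd))
    warning("records lacking FS/QD annotations pass the filter")
  if (is.null(fs)) fs <- rep(NA_real_, nrow(calls))
  if (is.null(qd)) qd <- rep(NA_real_, nrow(calls))
  bad <- (!is.na(fs) & fs > max_fs) | (!is.na(qd) & qd < min_qd)
  log_removal(calls, !bad, "site_annotations")
}

#' Remove calls at blacklisted sites or inside repeat regions
#'
#' Approximates RNA-seq false-positive screening with two blacklists: a
#' 1-based site list (e.g. known RNA-editing positions) and a BED table
#' of repeat regions (0-based half-open, so interval \[start, end) covers
#' 1-based positions start+1 .. end).
#'
#' @param calls calls data.frame.
#' @param editing_sites data.frame contig/pos (1-based) or NULL.
#' @param repeat_regions data.frame contig/start/end (BED) or NULL.
#' @return filtered calls.
#' @export
filter_blacklists <- function(calls, editing_sites = NULL,
                              repeat_regions = NULL) {
  if (nrow(calls) == 0) return(log_removal(calls, logical(0), "blacklist"))
  bad <- logical(nrow(calls))
  if (!is.null(editing_sites) && nrow(editing_sites) > 0) {
    key <- paste(calls$contig, calls$pos)
    bad <- bad | key %in% paste(editing_sites$contig, editing_sites$pos)
  }
  if (!is.null(repeat_regions) && nrow(repeat_regions) > 0) {
    for (i in seq_len(nrow(repeat_regions))) {
      hit <- calls$contig == repeat_regions$contig[i] &
        calls$pos > repeat_regions$start[i] &
        calls$pos <= repeat_regions$end[i]
      bad <- bad | hit
    }
  }
  log_removal(calls, !bad, "blacklist")
}

#' Keep RNA calls confirmed by whole-exome sequencing
#'
#' Retains records whose (contig, pos, ref, alt) key appears in the WES
#' call set — DNA confirmation of the RNA-level call.
#'
#' @param rna_calls calls data.frame.
#' @param wes_calls data.frame with contig/pos/ref/alt.
#' @return filtered calls.
#' @export
intersect_with_wes <- function(rna_calls, wes_calls) {
  if (nrow(rna_calls) == 0)
    return(log_removal(rna_calls, logical(0), "wes_overlap"))
  keep <- variant_key(rna_calls) %in% variant_key(wes_calls)
  log_removal(rna_calls, keep, "wes_overlap")
}

#' Select somatic non-synonymous variants
#'
#' Retains records present in the tumor exome, absent from the matched
#' normal exome (i.e. somatic, not germline), and annotated
#' non-synonymous.
#'
#' @param calls calls data.frame with an `effect` column.
#' @param tumor_wes,normal_wes key data.frames (contig/pos/ref/alt).
#' @return filtered calls.
#' @export
select_somatic_nonsynonymous <- function(calls, tumor_wes, normal_wes) {
  if (nrow(calls) == 0)
    return(log_removal(calls, logical(0), "somatic_nonsyn"))
  if (is.null(calls$effect)) stop_invalid("calls lack an 'effect' column")
  key <- variant_key(calls)
  keep <- key %in% variant_key(tumor_wes) &
    !(key %in% variant_key(normal_wes)) &
    calls$effect == "non_synonymous"
  log_removal(calls, keep, "somatic_nonsyn")
}

#' Run the full variant filter cascade
#'
#' Applies, in order: call quality, variant clusters, FS/QD site
#' annotations, blacklists, WES overlap, somatic non-synonymous
#' selection. Every stage only removes records.
#'
#' @param callset a `variant_callset` (from
#'   [generate_variant_callset()]) or a list with the same elements.
#' @param min_q,window,cluster,max_fs,min_qd stage thresholds.
#' @return filtered calls data.frame; attribute `removed` holds the
#'   per-stage removal counts.
#' @export
filter_cascade <- function(callset, min_q = 20, window = 35L, cluster = 3L,
                           max_fs = 30.0, min_qd = 2.0) {
  x <- filter_by_quality(callset$rna, min_q = min_q)
  x <- filter_variant_clusters(x, window = window, cluster = cluster)
  x <- filter_by_site_annotations(x, max_fs = max_fs, min_qd = min_qd)
  x <- filter_blacklists(x, callset$editing_sites, callset$repeats)
  x <- intersect_with_wes(x, callset$wes_tumor)
  select_somatic_nonsynonymous(x, callset$wes_tumor, callset$wes_normal)
}
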