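#' Poisson quantification of droplet digital PCR counts
#'
#' Converts positive-droplet counts to absolute allele copy numbers via
#' the Poisson occupancy inversion
#' `copies = -ln(1 - positives/total) * total` for the mutant and
#' wild-type channels, computes the variant allele frequency
#' `VAF = copies_mut / (copies_mut + copies_wt)`, and calls zygosity:
#' homozygous iff VAF strictly exceeds `hom_threshold` (default 0.90),
#' heterozygous otherwise.
#'
#' @param mut_positive,wt_positive mutant/wild-type positive droplet
#'   counts.
#' @param total_droplets total accepted droplets (> positives; an
#'   all-positive channel is saturated and rejected).
#' @param hom_threshold VAF above which the genotype is called
#'   homozygous (strict inequality; default 0.90).
#' @return object of class `ddpcr_result`: list with `total_droplets`,
#'   `mut_positive_droplets`, `wt_positive_droplets`, `est_mut_copies`,
#'   `est_wt_copies`, `vaf` (NA, flagged, when both copy estimates are
#'   0) and `zygosity` ("het"/"hom", NA when VAF undefined).
#' @examples
#' r <- ddpcr_quantify(500, 500, 1000)
#' c(r$est_mut_copies / 1000, r$vaf, r$zygosity)  # ln 2, 0.5, het
#' @export
ddpcr_quantify <- function(mut_positive, wt_positive, total_droplets,
                           hom_threshold = 0.90) {
  if (total_droplets <= 0) stop_invalid("'total_droplets' must be positive")
  for (v in c(mut_positive, wt_positive))
    if (v < 0 || v > total_droplets)
      stop_invalid("positive counts must lie in [0, total_droplets]")
  if (mut_positive == total_droplets || wt_positive == total_droplets)
    stop_invalid("saturated ddPCR channel (all droplets positive): copies not estimable")

  copies <- function(pos) -log(1 - pos / total_droplets) * total_droplets
  mc <- copies(mut_positive)
  wc <- copies(wt_positive)
  vaf <- if (mc + wc == 0) NA_real_ else mc / (mc + wc)
  out <- list(total_droplets = total_droplets,
              mut_positive_droplets = mut_positive,
              wt_positive_droplets = wt_positive,
              est_mut_copies = mc, est_wt_copies = wc, vaf = vaf,
              zygosity = if (is.na(vaf)) NA_character_ else
                ddpcr_zygosity(vaf, hom_threshold))
  class(out) <- "ddpcr_result"
  out
}

#' Zygosity call from a variant allele frequency
#'
#' @param vaf variant allele frequency in \[0, 1\] (vectorized).
#' @param hom_threshold homozygous iff `vaf > hom_threshold` (strict).
#' @return "hom" or "het" per element.
#' @export
ddpcr_zygosity <- function(vaf, hom_threshold = 0.90) {
  check_prob(vaf, "vaf")
  ifelse(vaf > hom_threshold, "hom", "het")
}

#' @export
print.ddpcr_result <- function(x, ...) {
  cat(sprintf("ddPCR: %d/%d mut+, %d/%d wt+ droplets -> %.1f mut / %.1f wt copies; VAF %.3f (%s)\n",
              x$mut_positive_droplets, x$total_droplets,
              x$wt_positive_droplets, x$total_droplets,
              x$est_mut_copies, x$est_wt_copies, x$vaf, x$zygosity))
  invisible(x)
}

#' Simulate droplet partitioning at known allele concentrations
#'
#' Benchmarking helper for the Poisson estimator: distributes
#' `mut_copies` and `wt_copies` template molecules over
#' `total_droplets` droplets (independent Poisson occupancy per channel)
#' and counts positive droplets.
#'
#' @param mut_copies,wt_copies true template copy numbers.
#' @param total_droplets droplet count.
#' @param seed RNG seed.
#' @return list with mut_positive, wt_positive, total_droplets.
#' @export
simulate_ddpcr <- function(mut_copies, wt_copies, total_droplets,
                           seed = 1L) {
  set.seed(seed)
  pos <- function(copies) sum(stats::rpois(total_droplets,
                                           copies / total_droplets) > 0)
  list(mut_positive = pos(mut_copies), wt_positive = pos(wt_copies),
       total_droplets = total_droplets)
}
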