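#' Write an expression matrix as TSV
#'
#' Genes in rows, samples in columns, header row of sample IDs with a
#' leading `gene` column.
#'
#' @param expr genes x samples numeric matrix.
#' @param path output file.
#' @export
write_expression_tsv <- function(expr, path) {
  check_expression_matrix(expr)
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression TSV written by [write_expression_tsv()]
#' @param path file path.
#' @return genes x samples numeric matrix.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write variant calls as VCF v4.2
#'
#' Serializes the `rna` data.frame of a [generate_variant_callset()]
#' result (or any data.frame with the same columns). FS, QD and the
#' coding effect go to INFO; per-sample allele depths to FORMAT AD
#' (ref,alt) and DP. Output is byte-deterministic for identical input.
#'
#' @param calls calls data.frame.
#' @param path output file.
#' @param sample sample column name.
#' @param contig_length contig length for the header.
#' @export
write_vcf <- function(calls, path, sample = "TUMOR", contig_length = 1e6) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", calls$contig[1],
            as.integer(contig_length)),
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Coding effect\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample), collapse = "\t")
  )
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t%.2f\tPASS\tFS=%.3f;QD=%.3f;EFF=%s\tAD:DP\t%d,%d:%d",
                  calls$contig, calls$pos, calls$id, calls$ref, calls$alt,
                  calls$qual, calls$fs, calls$qd, calls$effect,
                  calls$ref_depth, calls$alt_depth,
                  calls$ref_depth + calls$alt_depth)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF into the calls data.frame contract
#'
#' A minimal reader for VCFs written by [write_vcf()] (single sample,
#' INFO keys FS/QD/EFF, FORMAT AD:DP). For general VCFs use vcfR and
#' coerce to the same columns.
#'
#' @param path VCF file.
#' @return data.frame with id, contig, pos, ref, alt, qual, fs, qd,
#'   effect, ref_depth, alt_depth.
#' @export
read_vcf <- function(path) {
  ln <- readLines(path)
  body <- ln[!startsWith(ln, "#")]
  if (length(body) == 0)
    return(data.frame(id = character(), contig = character(),
                      pos = integer(), ref = character(), alt = character(),
                      qual = numeric(), fs = numeric(), qd = numeric(),
                      effect = character(), ref_depth = integer(),
                      alt_depth = integer(), stringsAsFactors = FALSE))
  f <- strsplit(body, "\t", fixed = TRUE)
  info_get <- function(info, key) {
    m <- regmatches(info, regexpr(paste0(key, "=[^;]+"), info))
    sub(paste0(key, "="), "", m)
  }
  info <- vapply(f, `[[`, "", 8L)
  gt <- vapply(f, `[[`, "", 10L)
  ad <- strsplit(vapply(strsplit(gt, ":", fixed = TRUE), `[[`, "", 1L),
                 ",", fixed = TRUE)
  data.frame(
    id = vapply(f, `[[`, "", 3L),
    contig = vapply(f, `[[`, "", 1L),
    pos = as.integer(vapply(f, `[[`, "", 2L)),
    ref = vapply(f, `[[`, "", 4L),
    alt = vapply(f, `[[`, "", 5L),
    qual = as.numeric(vapply(f, `[[`, "", 6L)),
    fs = as.numeric(info_get(info, "FS")),
    qd = as.numeric(info_get(info, "QD")),
    effect = info_get(info, "EFF"),
    ref_depth = as.integer(vapply(ad, `[[`, "", 1L)),
    alt_depth = as.integer(vapply(ad, `[[`, "", 2L)),
    stringsAsFactors = FALSE)
}

#' Read a BED blacklist (0-based half-open intervals)
#'
#' @param path BED file with at least contig, start, end columns.
#' @return data.frame contig/start/end.
#' @export
read_bed <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(ln)]
  f <- strsplit(ln, "\t", fixed = TRUE)
  for (i in seq_along(f)) {
    if (length(f[[i]]) < 3L ||
        is.na(suppressWarnings(as.integer(f[[i]][2]))) ||
        is.na(suppressWarnings(as.integer(f[[i]][3]))))
      stop_invalid("malformed BED line %d in '%s'", i, path)
  }
  data.frame(contig = vapply(f, `[[`, "", 1L),
             start = as.integer(vapply(f, `[[`, "", 2L)),
             end = as.integer(vapply(f, `[[`, "", 3L)),
             stringsAsFactors = FALSE)
}

#' Write a BED blacklist
#' @param bed data.frame contig/start/end (0-based half-open).
#' @param path output file.
#' @export
write_bed <- function(bed, path) {
  writeLines(sprintf("%s\t%d\t%d", bed$contig, bed$start, bed$end), path)
  invisible(path)
}

#' Read a 1-based site list (contig, pos TSV, no header)
#' @param path file path.
#' @return data.frame contig/pos.
#' @export
read_site_list <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(contig = df[[1]], pos = as.integer(df[[2]]),
             stringsAsFactors = FALSE)
}

#' Read gene sets in GMT format
#'
#' One set per tab-separated line: name, description, member genes.
#'
#' @param path GMT file.
#' @return named list of character vectors of member gene IDs.
#' @export
read_gmt <- function(path) {
  f <- strsplit(readLines(path), "\t", fixed = TRUE)
  f <- f[vapply(f, length, 1L) >= 3L]
  stats::setNames(lapply(f, function(x) unique(x[-(1:2)])),
                  vapply(f, `[[`, "", 1L))
}

#' Write a cell genotype matrix as TSV
#'
#' Variants in rows, cells in columns, values MUT/WT/NOCALL.
#' @param geno a `cell_genotype_matrix` or character matrix of calls.
#' @param path output file.
#' @export
write_genotype_tsv <- function(geno, path) {
  calls <- if (inherits(geno, "cell_genotype_matrix")) geno$calls else geno
  short <- matrix(c(MUT_EXPRESSED = "MUT", WT_EXPRESSED = "WT",
                    NO_CALL = "NOCALL")[calls],
                  nrow = nrow(calls), dimnames = dimnames(calls))
  df <- data.frame(variant = rownames(short), short, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
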