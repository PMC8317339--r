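#' Background-error filter configuration
#'
#' Bundles the thresholds of the four background-error selection rules:
#' (1) reference-matching bases never count as errors (implicit in the
#' counting itself), (2) bases below a Phred quality floor are discarded,
#' (3) genomic positions whose post-filter depth falls below a floor in any
#' sample of the comparison are removed entirely, and (4) alternate alleles
#' whose allele fraction exceeds a germline threshold in either member of a
#' cfDNA/gDNA pair are excluded from error counting in both members.
#' An optional blacklist removes known (or somatically called) variants the
#' same way rule 4 does.
#'
#' @param min_base_quality Phred floor for individual base calls
#'   (default 30, i.e. an error probability of 1e-3).
#' @param min_depth Minimum post-quality-filter depth for a position to be
#'   eligible (default 500).
#' @param germline_af_threshold Allele fraction above which an alternate
#'   allele is treated as germline variation and masked (default 0.01).
#' @param variant_blacklist Optional `data.frame` with columns
#'   `chrom`, `pos` (1-based), `alt`: additional alleles to mask.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_base_quality = 30L,
                          min_depth = 500L,
                          germline_af_threshold = 0.01,
                          variant_blacklist = NULL) {
  if (min_base_quality <= 0 || min_depth <= 0)
    stop("min_base_quality and min_depth must be positive")
  if (germline_af_threshold <= 0 || germline_af_threshold >= 1)
    stop("germline_af_threshold must lie in (0, 1)")
  if (!is.null(variant_blacklist)) {
    variant_blacklist <- as.data.table(variant_blacklist)
    need <- c("chrom", "pos", "alt")
    if (!all(need %in% names(variant_blacklist)))
      stop("variant_blacklist needs columns chrom, pos, alt")
    if (!all(variant_blacklist$alt %in% BASES))
      stop("variant_blacklist alt alleles must be A/C/G/T")
  }
  structure(
    list(min_base_quality = as.integer(min_base_quality),
         min_depth = as.integer(min_depth),
         germline_af_threshold = germline_af_threshold,
         variant_blacklist = variant_blacklist),
    class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat("filter_config:\n")
  cat("  min base quality  Q", x$min_base_quality, "\n", sep = "")
  cat("  min depth         ", x$min_depth, "x\n", sep = "")
  cat("  germline AF mask  > ", x$germline_af_threshold, "\n", sep = "")
  cat("  blacklist         ",
      if (is.null(x$variant_blacklist)) "none"
      else paste(nrow(x$variant_blacklist), "alleles"), "\n", sep = "")
  invisible(x)
}

#' Read a variant blacklist from VCF or 3-column TSV
#'
#' Accepts either a VCF (`*.vcf`) or a headerless/headered TSV with columns
#' chrom, pos (1-based), alt. Multi-allelic VCF rows are expanded; non-SNV
#' alleles are dropped.
#'
#' @param path File path.
#' @return `data.table` with columns `chrom`, `pos`, `alt`.
#' @export
read_variant_blacklist <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "#")]
    if (length(ln) == 0) return(data.table(chrom = character(), pos = integer(), alt = character()))
    f <- tstrsplit(ln, "\t", fixed = TRUE)
    dt <- data.table(chrom = f[[1]], pos = as.integer(f[[2]]),
                     ref = f[[4]], alt = f[[5]])
    dt <- dt[, .(alt = unlist(strsplit(alt, ",", fixed = TRUE))),
             by = .(chrom, pos, ref)]
    dt <- dt[nchar(ref) == 1L & alt %in% BASES]
    dt[, .(chrom, pos, alt)]
  } else {
    dt <- fread(path, header = "auto")
    setnames(dt, seq_len(3), c("chrom", "pos", "alt"))
    dt[, .(chrom = as.character(chrom), pos = as.integer(pos),
           alt = as.character(alt))]
  }
}
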