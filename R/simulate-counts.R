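#' Simulate pileup-level allele counts
#'
#' Draws `SiteCounts` tables directly at the pileup level: at every panel
#' position and sample, each alternate allele's depth is
#' `Binomial(depth, class rate)` for the sample group's planted rate, and
#' planted germline alleles add `Binomial(depth, AF)` reads. The
#' reference-allele depth absorbs the remainder so each position's total
#' equals `depth` exactly. Counts mode has no read coordinates, so
#' breakpoint end effects and UMI structure do not apply — it exists to
#' exercise the filtering and statistics quickly at full panel scale.
#'
#' @param config A [sim_config()] with `mode = "counts"`.
#' @return List: `counts` (named list of `SiteCounts`), `meta` (sample
#'   sheet), `ledger` (planted truth: `germline`, `class_rates` per group,
#'   `panel_ref`), `panel` (`data.table` chrom/start/end, 1-based closed).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$mode != "counts") stop("config mode must be 'counts'")
  set.seed(config$seed)
  meta <- sim_sample_meta(config)
  truth <- sim_panel_truth(config)
  ref <- truth$ref
  n <- config$panel_bp
  d <- config$depth
  ref_idx <- match(ref, BASES)
  rows_by_ref <- lapply(setNames(BASES, BASES), function(b) which(ref == b))

  counts <- vector("list", nrow(meta))
  names(counts) <- meta$sample_id
  for (i in seq_len(nrow(meta))) {
    rates <- if (meta$sample_type[i] == "cfDNA") config$rates_cfdna
             else config$rates_gdna
    alt_mat <- matrix(0L, n, 4, dimnames = list(NULL, BASES))
    for (cls in SUBSTITUTION_CLASSES) {
      r <- rates[cls]
      if (r <= 0) next
      rows <- rows_by_ref[[class_ref(cls)]]
      if (!length(rows)) next
      alt_mat[rows, class_alt(cls)] <-
        alt_mat[rows, class_alt(cls)] + rbinom(length(rows), d, r)
    }
    if (nrow(truth$germline) > 0) {
      g <- truth$germline
      alt_mat[cbind(g$pos, match(g$alt, BASES))] <-
        alt_mat[cbind(g$pos, match(g$alt, BASES))] + rbinom(nrow(g), d, g$af)
    }
    non_ref <- rowSums(alt_mat) - alt_mat[cbind(seq_len(n), ref_idx)]
    alt_mat[cbind(seq_len(n), ref_idx)] <- pmax(0L, d - as.integer(non_ref))
    dt <- data.table(chrom = config$chrom, pos = seq_len(n), ref_base = ref,
                     depth = as.integer(rowSums(alt_mat)),
                     A = alt_mat[, "A"], C = alt_mat[, "C"],
                     G = alt_mat[, "G"], T = alt_mat[, "T"])
    setkey(dt, chrom, pos)
    counts[[i]] <- dt
  }
  list(counts = counts,
       meta = meta,
       ledger = list(germline = truth$germline,
                     class_rates = list(cfDNA = config$rates_cfdna,
                                        gDNA = config$rates_gdna),
                     panel_ref = ref,
                     seed = config$seed),
       panel = data.table(chrom = config$chrom, start = 1L, end = n))
}
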