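#' Per-class background rate presets
#'
#' Class rates (errors per sequenced base at positions carrying the
#' class's reference base) emulating the magnitudes seen in targeted deep
#' sequencing of healthy-donor samples: a gDNA-like sample has a flat
#' background of 9e-6 per directional class (total 2.7e-5 at uniform base
#' composition); a cfDNA-like sample carries the same background with
#' C>T and G>A elevated by cytosine deamination to 6.9e-5 each
#' (total 5.7e-5). The two presets differ only in the deamination pair.
#'
#' @param type `"cfdna"` or `"gdna"`.
#' @return Named numeric vector over the 12 directional classes.
#' @export
preset_class_rates <- function(type = c("cfdna", "gdna")) {
  type <- match.arg(type)
  r <- setNames(rep(9e-6, 12), SUBSTITUTION_CLASSES)
  if (type == "cfdna") r[c("C>T", "G>A")] <- 6.9e-5
  r
}

#' Synthetic-data configuration
#'
#' Describes one simulated cfDNA-vs-gDNA experiment. `mode = "counts"`
#' draws allele depths directly at the pileup level (fast; no reads, no
#' UMI structure); `mode = "reads"` emits aligned paired reads with UMI
#' families, molecule-level damage, first-cycle PCR errors, and per-read
#' sequencer errors, so the whole read pipeline can run end to end.
#'
#' @param mode `"counts"` or `"reads"`.
#' @param seed Integer seed; every simulation is deterministic given the
#'   config.
#' @param panel_bp Panel footprint in bp (one synthetic contig).
#' @param chrom Contig name.
#' @param depth Per-position depth in counts mode.
#' @param n_pairs Number of cfDNA/gDNA sample pairs per group.
#' @param rates_cfdna,rates_gdna Named 12-vectors of per-class rates; in
#'   reads mode these are molecule-level damage rates (they propagate to
#'   every UMI-family member, as DNA lesions do).
#' @param end_effect `NULL` or `list(class=, first_k_bp=, multiplier=)`:
#'   multiplies the named class's molecule-level rate within the first
#'   `first_k_bp` bases of each fragment end (reads mode; emulates
#'   shearing-induced oxidation). Applied to gDNA-like samples.
#' @param germline_n_het,germline_n_hom Numbers of heterozygous (AF 0.5)
#'   and homozygous (AF 1.0) germline variant sites planted on the panel,
#'   shared by every sample (all samples behave as one donor's genotype).
#' @param umi_mean_progeny Mean UMI-family size; family sizes are drawn
#'   zero-truncated Poisson with this mean (default 2.79).
#' @param pcr_error_rate Per-base probability of a first-cycle PCR error
#'   on a template molecule (family-wide, reads mode).
#' @param seq_error_rate Per-base probability of a sequencer error on an
#'   individual read (reads mode; removable by consensus).
#' @param quality_levels,quality_probs Discrete Phred quality distribution
#'   for base calls (default: 5% Q20, 15% Q33, 80% Q39, an RTA-like
#'   binning; sequencer-error bases draw from the same distribution).
#' @param fragment_length_cfdna,fragment_length_gdna Template lengths in
#'   bp (167 bp nucleosomal cfDNA; 450 bp sonicated gDNA).
#' @param read_length Read length (paired 100 bp).
#' @param n_fragments Template molecules per sample (reads mode); either
#'   one number for both groups or a named vector
#'   `c(cfDNA = ..., gDNA = ...)`.
#' @return A `sim_config` object (validated list).
#' @export
sim_config <- function(mode = c("counts", "reads"),
                       seed = 1L,
                       panel_bp = 50000L,
                       chrom = "panel1",
                       depth = 1000L,
                       n_pairs = 5L,
                       rates_cfdna = preset_class_rates("cfdna"),
                       rates_gdna = preset_class_rates("gdna"),
                       end_effect = list(class = "C>A", first_k_bp = 5L,
                                         multiplier = 5),
                       germline_n_het = 0L,
                       germline_n_hom = 0L,
                       umi_mean_progeny = 2.79,
                       pcr_error_rate = 0,
                       seq_error_rate = 0,
                       quality_levels = c(20L, 33L, 39L),
                       quality_probs = c(0.05, 0.15, 0.80),
                       fragment_length_cfdna = 167L,
                       fragment_length_gdna = 450L,
                       read_length = 100L,
                       n_fragments = 10000L) {
  mode <- match.arg(mode)
  norm_rates <- function(r, what) {
    out <- setNames(numeric(12), SUBSTITUTION_CLASSES)
    if (length(r)) {
      check_class(names(r))
      out[names(r)] <- r
    }
    if (any(out < 0 | out > 1)) stop(what, ": rates must lie in [0, 1]")
    out
  }
  rates_cfdna <- norm_rates(rates_cfdna, "rates_cfdna")
  rates_gdna <- norm_rates(rates_gdna, "rates_gdna")
  if (length(n_fragments) == 1L)
    n_fragments <- c(cfDNA = n_fragments, gDNA = n_fragments)
  if (!all(c("cfDNA", "gDNA") %in% names(n_fragments)))
    stop("n_fragments must be one number or named c(cfDNA=, gDNA=)")
  if (panel_bp < 1 || depth < 1 || n_pairs < 1 || any(n_fragments < 1))
    stop("panel_bp, depth, n_pairs, n_fragments must be positive")
  if (!is.null(end_effect)) {
    stopifnot(is.list(end_effect),
              all(c("class", "first_k_bp", "multiplier") %in% names(end_effect)))
    check_class(end_effect$class)
    if (end_effect$multiplier < 0) stop("end_effect multiplier must be >= 0")
  }
  if (umi_mean_progeny < 1) stop("umi_mean_progeny must be >= 1")
  if (pcr_error_rate < 0 || pcr_error_rate > 1 ||
      seq_error_rate < 0 || seq_error_rate > 1)
    stop("error rates must lie in [0, 1]")
  stopifnot(length(quality_levels) == length(quality_probs),
            abs(sum(quality_probs) - 1) < 1e-8)
  if (mode == "reads") {
    for (fl in c(fragment_length_cfdna, fragment_length_gdna)) {
      if (fl < read_length)
        stop("fragment length (", fl, ") must be >= read_length (",
             read_length, ")")
      if (panel_bp < fl)
        stop("panel (", panel_bp, " bp) shorter than fragment length (",
             fl, " bp)")
    }
  }
  structure(list(
    mode = mode, seed = as.integer(seed), panel_bp = as.integer(panel_bp),
    chrom = chrom, depth = as.integer(depth), n_pairs = as.integer(n_pairs),
    rates_cfdna = rates_cfdna, rates_gdna = rates_gdna,
    end_effect = end_effect,
    germline_n_het = as.integer(germline_n_het),
    germline_n_hom = as.integer(germline_n_hom),
    umi_mean_progeny = umi_mean_progeny,
    pcr_error_rate = pcr_error_rate, seq_error_rate = seq_error_rate,
    quality_levels = as.integer(quality_levels),
    quality_probs = quality_probs,
    fragment_length_cfdna = as.integer(fragment_length_cfdna),
    fragment_length_gdna = as.integer(fragment_length_gdna),
    read_length = as.integer(read_length),
    n_fragments = setNames(as.integer(n_fragments), names(n_fragments))),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config (", x$mode, " mode, seed ", x$seed, ")\n", sep = "")
  cat("  panel ", x$panel_bp, " bp, ", x$n_pairs,
      " cfDNA/gDNA pairs\n", sep = "")
  if (x$mode == "counts") cat("  depth ", x$depth, "x\n", sep = "")
  else cat("  ", x$n_fragments[["cfDNA"]], "/", x$n_fragments[["gDNA"]],
           " fragments/sample (cfDNA/gDNA), mean progeny ",
           x$umi_mean_progeny, "\n", sep = "")
  cat("  total planted rates: cfDNA ",
      signif(sum(x$rates_cfdna) / 4, 3), ", gDNA ",
      signif(sum(x$rates_gdna) / 4, 3), "\n", sep = "")
  invisible(x)
}

# zero-truncated Poisson sampler with a given (truncated) mean
rztpois <- function(n, mean_truncated) {
  lambda <- if (mean_truncated <= 1) 1e-8 else
    stats::uniroot(function(l) l / (1 - exp(-l)) - mean_truncated,
                   c(1e-8, mean_truncated + 10))$root
  p0 <- stats::ppois(0, lambda)
  stats::qpois(p0 + runif(n) * (1 - p0), lambda)
}

# sample-sheet shared by both simulators
sim_sample_meta <- function(config) {
  data.table(
    sample_id = c(paste0("cf_", seq_len(config$n_pairs)),
                  paste0("g_", seq_len(config$n_pairs))),
    subject_id = rep(paste0("S", seq_len(config$n_pairs)), 2),
    sample_type = rep(c("cfDNA", "gDNA"), each = config$n_pairs),
    replicate_id = "rep1",
    pair_id = rep(paste0("P", seq_len(config$n_pairs)), 2))
}

# draw the shared panel reference sequence and germline variant set
sim_panel_truth <- function(config) {
  ref <- sample(BASES, config$panel_bp, replace = TRUE)
  n_var <- config$germline_n_het + config$germline_n_hom
  germline <- data.table(chrom = character(), pos = integer(),
                         ref = character(), alt = character(),
                         af = numeric())
  if (n_var > 0) {
    pos <- sort(sample.int(config$panel_bp, n_var))
    alt <- vapply(ref[pos], function(r) sample(setdiff(BASES, r), 1),
                  character(1))
    germline <- data.table(
      chrom = config$chrom, pos = pos, ref = ref[pos], alt = alt,
      af = sample(rep(c(0.5, 1.0),
                      c(config$germline_n_het, config$germline_n_hom))))
  }
  list(ref = ref, germline = germline)
}
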