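#' Tally per-position allele depths from observations
#'
#' Applies the base-quality filter (rule 2) and counts retained bases per
#' genomic position and observed allele. Positions are kept in the table
#' whatever their depth; the depth rule (rule 3) is applied downstream so
#' that eligibility can be evaluated jointly across samples.
#'
#' @param obs Observation table ([stream_observations()] output or
#'   [des_consensus()] output).
#' @param filter A [filter_config()].
#' @return `SiteCounts` `data.table`: `chrom`, `pos`, `ref_base`,
#'   `depth` (retained bases), and allele depths `A`, `C`, `G`, `T`.
#' @export
build_site_counts <- function(obs, filter = filter_config()) {
  obs <- as.data.table(obs)
  empty <- data.table(chrom = character(), pos = integer(),
                      ref_base = character(), depth = integer(),
                      A = integer(), C = integer(), G = integer(),
                      T = integer())
  if (nrow(obs) == 0) return(empty)
  keep <- obs[base_quality >= filter$min_base_quality &
                obs_base %chin% BASES & ref_base %chin% BASES]
  if (nrow(keep) == 0) return(empty)
  counts <- dcast(keep[, .N, by = .(chrom, pos, ref_base, obs_base)],
                  chrom + pos + ref_base ~ factor(obs_base, levels = BASES),
                  value.var = "N", fill = 0L, drop = c(TRUE, FALSE))
  counts[, depth := A + C + G + T]
  setcolorder(counts, c("chrom", "pos", "ref_base", "depth", BASES))
  setkey(counts, chrom, pos)
  counts[]
}

#' Mask putative germline alleles across a cfDNA/gDNA pair
#'
#' Rule 4: an alternate allele whose allele fraction exceeds the germline
#' threshold in *either* member of a matched pair is excluded from error
#' counting in *both* members. Fractions are computed on the
#' post-quality-filter depths, before any masking. Alleles on the filter's
#' blacklist are masked unconditionally. Other alternate alleles at the
#' same site remain countable.
#'
#' @param counts_a,counts_b `SiteCounts` tables of the two pair members
#'   (`counts_b` may be `NULL` for an unpaired sample, in which case only
#'   `counts_a` and the blacklist contribute).
#' @param filter A [filter_config()].
#' @return Mask `data.table` with columns `chrom`, `pos`, `alt`, `source`
#'   (`"af"` or `"blacklist"`).
#' @export
apply_pairwise_variant_exclusion <- function(counts_a, counts_b,
                                             filter = filter_config()) {
  af_mask <- function(counts) {
    if (is.null(counts) || nrow(counts) == 0)
      return(data.table(chrom = character(), pos = integer(), alt = character()))
    parts <- lapply(BASES, function(b) {
      idx <- which(counts$ref_base != b & counts$depth > 0 &
                     counts[[b]] / counts$depth > filter$germline_af_threshold)
      if (!length(idx)) NULL
      else data.table(chrom = counts$chrom[idx], pos = counts$pos[idx],
                      alt = b)
    })
    out <- rbindlist(parts)
    if (ncol(out) == 0)
      out <- data.table(chrom = character(), pos = integer(),
                        alt = character())
    out
  }
  mask <- rbind(af_mask(counts_a), af_mask(counts_b))
  mask <- unique(mask)[, source := "af"]
  if (!is.null(filter$variant_blacklist)) {
    bl <- filter$variant_blacklist[, .(chrom = as.character(chrom),
                                       pos = as.integer(pos),
                                       alt = as.character(alt),
                                       source = "blacklist")]
    mask <- unique(rbind(mask, bl), by = c("chrom", "pos", "alt"))
  }
  setkey(mask, chrom, pos)
  mask[]
}

# positions meeting the depth rule in this table and every pair table
eligible_positions <- function(counts, pair_counts_list, filter,
                               exclude_positions = NULL) {
  elig <- counts[depth >= filter$min_depth, .(chrom, pos)]
  for (pc in pair_counts_list) {
    if (is.null(pc)) next
    elig <- elig[pc[depth >= filter$min_depth, .(chrom, pos)],
                 on = c("chrom", "pos"), nomatch = 0L]
  }
  if (!is.null(exclude_positions) && nrow(exclude_positions) > 0)
    elig <- elig[!as.data.table(exclude_positions)[, .(chrom, pos)],
                 on = c("chrom", "pos")]
  elig
}

#' Compute a sample's background error profile
#'
#' Applies the depth rule (3) jointly with the sample's pair member(s),
#' removes masked (germline / blacklisted) alleles from the error counts,
#' and tallies the 12 substitution classes. Per-class denominators are the
#' eligible sequenced bases at positions carrying the class's reference
#' base (`denominator = "opportunity"`), or the total eligible bases
#' (`denominator = "total"`).
#'
#' @param counts `SiteCounts` table of the sample.
#' @param mask Allele mask from [apply_pairwise_variant_exclusion()]
#'   (or `NULL`).
#' @param filter A [filter_config()].
#' @param pair_counts Optional `SiteCounts` (or list of them) whose depth
#'   must also reach `min_depth` for a position to stay eligible.
#' @param sample_id Sample label for the profile.
#' @param exclude_positions Optional `data.table` (`chrom`, `pos`) of
#'   positions to drop before profiling (the hit-list exclusion analysis).
#' @param denominator `"opportunity"` or `"total"`.
#' @return An [error_profile()].
#' @export
compute_error_profile <- function(counts, mask = NULL,
                                  filter = filter_config(),
                                  pair_counts = NULL,
                                  sample_id = "sample",
                                  exclude_positions = NULL,
                                  denominator = c("opportunity", "total")) {
  denominator <- match.arg(denominator)
  if (!is.null(pair_counts) && is.data.frame(pair_counts))
    pair_counts <- list(pair_counts)
  elig <- eligible_positions(counts, pair_counts, filter, exclude_positions)
  sub <- counts[elig, on = c("chrom", "pos"), nomatch = 0L]
  if (nrow(sub) == 0)
    return(error_profile(sample_id, integer(0), numeric(0),
                         denominator = denominator))
  # class tallies from the wide columns: per ref base, sum each alt column,
  # then subtract the masked alleles (mask tables are small)
  agg <- sub[, c(lapply(.SD, function(x) sum(as.numeric(x))), list(n_pos = .N)),
             by = ref_base, .SDcols = c(BASES, "depth")]
  counts_vec <- setNames(numeric(12), SUBSTITUTION_CLASSES)
  for (cls in SUBSTITUTION_CLASSES) {
    row <- which(agg$ref_base == class_ref(cls))
    if (length(row))
      counts_vec[cls] <- agg[[class_alt(cls)]][row]
  }
  if (!is.null(mask) && nrow(mask) > 0) {
    msub <- sub[mask[, .(chrom, pos, alt)], on = c("chrom", "pos"),
                nomatch = 0L][alt != ref_base]
    if (nrow(msub) > 0) {
      ad <- as.matrix(msub[, BASES, with = FALSE])[
        cbind(seq_len(nrow(msub)), match(msub$alt, BASES))]
      mc <- data.table(cls = sub_class(msub$ref_base, msub$alt),
                       n = as.numeric(ad))[, .(n = sum(n)), by = cls]
      counts_vec[mc$cls] <- counts_vec[mc$cls] - mc$n
    }
  }
  error_profile(sample_id,
                error_counts = counts_vec,
                eligible_bases = setNames(agg$depth, agg$ref_base),
                eligible_positions = setNames(agg$n_pos, agg$ref_base),
                denominator = denominator)
}

#' Percentage of eligible positions with no background error
#'
#' @inheritParams compute_error_profile
#' @return Percentage in `[0, 100]`, or `NA` if no position is eligible.
#' @export
error_free_fraction <- function(counts, mask = NULL,
                                filter = filter_config(),
                                pair_counts = NULL,
                                exclude_positions = NULL) {
  if (!is.null(pair_counts) && is.data.frame(pair_counts))
    pair_counts <- list(pair_counts)
  elig <- eligible_positions(counts, pair_counts, filter, exclude_positions)
  sub <- counts[elig, on = c("chrom", "pos"), nomatch = 0L]
  if (nrow(sub) == 0) return(NA_real_)
  long <- melt(sub, id.vars = c("chrom", "pos", "ref_base", "depth"),
               measure.vars = BASES, variable.name = "alt",
               value.name = "ad", variable.factor = FALSE)
  errs <- long[alt != ref_base & ad > 0]
  if (!is.null(mask) && nrow(mask) > 0)
    errs <- errs[!mask[, .(chrom, pos, alt)], on = c("chrom", "pos", "alt")]
  n_err_pos <- uniqueN(errs[, .(chrom, pos)])
  100 * (1 - n_err_pos / nrow(sub))
}

#' Per-position, per-class error rates across samples
#'
#' Builds the position-resolved error table used for distribution plots and
#' per-position group tests. A position is eligible only if every sample
#' reaches `min_depth` there; ineligible positions are absent for all
#' samples. Rates pool nothing: one row per (position, class, sample),
#' plus `"total"` rows pooling the three alternate alleles of the position.
#'
#' @param counts_list Named list of `SiteCounts` tables (names = sample
#'   ids).
#' @param masks Either one mask table applied to all samples or a named
#'   list parallel to `counts_list`.
#' @param filter A [filter_config()].
#' @return `data.table`: `chrom`, `pos`, `ref_base`, `class` (a
#'   directional class or `"total"`), `sample_id`, `errors`, `depth`,
#'   `rate`.
#' @export
position_error_table <- function(counts_list, masks = NULL,
                                 filter = filter_config()) {
  stopifnot(length(counts_list) >= 1, !is.null(names(counts_list)))
  common <- NULL
  for (ct in counts_list) {
    e <- ct[depth >= filter$min_depth, .(chrom, pos)]
    common <- if (is.null(common)) e
              else common[e, on = c("chrom", "pos"), nomatch = 0L]
  }
  out <- vector("list", length(counts_list))
  for (i in seq_along(counts_list)) {
    sid <- names(counts_list)[i]
    mask <- if (is.data.frame(masks)) masks else masks[[sid]]
    sub <- counts_list[[i]][common, on = c("chrom", "pos"), nomatch = 0L]
    long <- melt(sub, id.vars = c("chrom", "pos", "ref_base", "depth"),
                 measure.vars = BASES, variable.name = "alt",
                 value.name = "ad", variable.factor = FALSE)
    long <- long[alt != ref_base]
    if (!is.null(mask) && nrow(mask) > 0)
      long <- long[!mask[, .(chrom, pos, alt)], on = c("chrom", "pos", "alt")]
    per_class <- long[, .(chrom, pos, ref_base,
                          class = sub_class(ref_base, alt),
                          sample_id = sid, errors = ad, depth,
                          rate = ad / depth)]
    per_site <- long[, .(class = "total", sample_id = sid,
                         errors = sum(ad), depth = depth[1],
                         rate = sum(ad) / depth[1]),
                     by = .(chrom, pos, ref_base)]
    out[[i]] <- rbind(per_class, per_site, use.names = TRUE)
  }
  res <- rbindlist(out)
  setkey(res, chrom, pos, class, sample_id)
  res[]
}

#' Error rates by distance from the fragment breakpoint
#'
#' Tallies errors and eligible bases in ten 5-bp bins of
#' `dist_from_breakpoint` (read positions 1-50). Only bases at positions
#' passing the depth rule (jointly with `pair_counts`) and alleles not
#' masked as germline are counted; bases beyond 50 bp from the 5' end are
#' outside the analysis.
#'
#' @param obs Observation table carrying `dist_from_breakpoint`.
#' @param mask Allele mask (or `NULL`).
#' @param filter A [filter_config()].
#' @param counts Optional precomputed `SiteCounts` for the depth rule
#'   (recomputed from `obs` when `NULL`).
#' @param pair_counts Optional pair `SiteCounts` (or list) for joint depth
#'   eligibility.
#' @param sample_id Sample label.
#' @return A [fragment_bin_profile_obj()].
#' @export
fragment_bin_profile <- function(obs, mask = NULL, filter = filter_config(),
                                 counts = NULL, pair_counts = NULL,
                                 sample_id = "sample") {
  obs <- as.data.table(obs)
  if (is.null(counts)) counts <- build_site_counts(obs, filter)
  if (!is.null(pair_counts) && is.data.frame(pair_counts))
    pair_counts <- list(pair_counts)
  elig <- eligible_positions(counts, pair_counts, filter)
  keep <- obs[base_quality >= filter$min_base_quality &
                obs_base %chin% BASES & ref_base %chin% BASES &
                dist_from_breakpoint <= 50L]
  keep <- keep[elig, on = c("chrom", "pos"), nomatch = 0L]
  keep[, bin := fragment_bin(dist_from_breakpoint)]
  bin_elig <- matrix(0, 10, 4, dimnames = list(paste0("bin", 1:10), BASES))
  tot <- keep[, .N, by = .(bin, ref_base)]
  bin_elig[cbind(tot$bin, match(tot$ref_base, BASES))] <- tot$N
  errs <- keep[obs_base != ref_base]
  if (!is.null(mask) && nrow(mask) > 0)
    errs <- errs[!mask[, .(chrom, pos, alt = alt)],
                 on = c("chrom", "pos", obs_base = "alt")]
  bin_cnt <- matrix(0, 10, 12,
                    dimnames = list(paste0("bin", 1:10), SUBSTITUTION_CLASSES))
  if (nrow(errs) > 0) {
    ec <- errs[, .N, by = .(bin, cls = sub_class(ref_base, obs_base))]
    bin_cnt[cbind(ec$bin, match(ec$cls, SUBSTITUTION_CLASSES))] <- ec$N
  }
  fragment_bin_profile_obj(sample_id, bin_cnt, bin_elig)
}
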