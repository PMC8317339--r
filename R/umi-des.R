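#' Group observations into UMI families
#'
#' A UMI family is the set of read pairs descending from one tagged
#' template molecule: all reads sharing the UMI sequence, the fragment's
#' chromosome and outer coordinates, and the strand of read 1 (so the two
#' strands of one original duplex stay separate under a single-strand UMI
#' scheme). Adds a `family_id` column to the observation table.
#'
#' @param obs Observation `data.table` from [stream_observations()].
#' @param umi_merge_hamming If 1, UMIs within Hamming distance 1 of a more
#'   abundant UMI on the same fragment key are merged into it before
#'   grouping (off by default; a 4-bp UMI over-merges easily).
#' @return List with `obs` (input plus `family_id`) and `families`
#'   (`data.table`: `family_id`, key columns, `family_size` = number of
#'   distinct read pairs).
#' @export
group_families <- function(obs, umi_merge_hamming = 0L) {
  obs <- copy(as.data.table(obs))
  if (nrow(obs) == 0) {
    return(list(obs = obs[, family_id := integer(0)],
                families = data.table(family_id = integer(), umi = character(),
                                      chrom = character(), fragment_start = integer(),
                                      fragment_end = integer(), fragment_strand = character(),
                                      family_size = integer())))
  }
  if (umi_merge_hamming >= 1L) obs <- merge_umis_hamming1(obs)
  obs[, family_id := .GRP,
      by = .(umi, chrom, fragment_start, fragment_end, fragment_strand)]
  families <- obs[, .(umi = umi[1], chrom = chrom[1],
                      fragment_start = fragment_start[1],
                      fragment_end = fragment_end[1],
                      fragment_strand = fragment_strand[1],
                      family_size = uniqueN(read_id)),
                  by = family_id]
  list(obs = obs, families = families)
}

# Merge low-count UMIs into a Hamming-distance-1 neighbour with more read
# pairs on the same fragment key. 4-bp UMIs only have 12 neighbours each.
merge_umis_hamming1 <- function(obs) {
  key_cols <- c("chrom", "fragment_start", "fragment_end", "fragment_strand")
  tab <- obs[, .(n = uniqueN(read_id)), by = c(key_cols, "umi")]
  setorder(tab, -n)
  tab[, canon := umi]
  grps <- split(seq_len(nrow(tab)), tab[, do.call(paste, .SD), .SDcols = key_cols])
  for (idx in grps) {
    if (length(idx) < 2) next
    umis <- tab$umi[idx]
    for (j in seq_along(umis)[-1]) {
      for (k in seq_len(j - 1)) {
        if (hamming1(umis[j], umis[k])) {
          tab$canon[idx[j]] <- tab$canon[idx[k]]
          break
        }
      }
    }
  }
  obs[tab, umi := i.canon, on = c(key_cols, "umi")]
  obs
}

hamming1 <- function(a, b) {
  if (nchar(a) != nchar(b)) return(FALSE)
  sum(utf8ToInt(a) != utf8ToInt(b)) == 1L
}

#' Collapse UMI families to consensus observations (digital error
#' suppression)
#'
#' Within each family and genomic position, every member base call votes
#' (both mates vote where they overlap). The consensus base must carry a
#' strict majority of the votes — ties and pluralities at or below 50%
#' drop the position from the family entirely, so a 2-member family with
#' one discordant base contributes nothing at that position. Singleton
#' families pass through unchanged. Errors introduced at or before the
#' first PCR cycle are shared by every member and therefore survive
#' consensus; errors private to one read (sequencer noise, late PCR) are
#' voted away wherever redundancy exists.
#'
#' The consensus base quality is the maximum supporting member quality at
#' the position, and `agreement_fraction` records the supporting share.
#'
#' @param grouped Result of [group_families()], or an observation table
#'   already carrying `family_id`.
#' @param consensus_rule `"majority"` (strict majority, default) or
#'   `"unanimous"` (any disagreement drops the position).
#' @return Consensus observation `data.table`: one row per (family,
#'   position) that survives, with columns as in [stream_observations()]
#'   plus `family_id`, `family_size` (distinct read pairs), `n_voting`,
#'   `agreement_fraction`. `read_id` holds the family's first read id;
#'   `mate` is 1.
#' @export
des_consensus <- function(grouped, consensus_rule = c("majority", "unanimous")) {
  consensus_rule <- match.arg(consensus_rule)
  obs <- if (is.data.table(grouped)) grouped else grouped$obs
  if (is.null(obs$family_id)) stop("observations lack family_id; run group_families()")
  if (nrow(obs) == 0) {
    out <- copy(obs)
    out[, `:=`(family_size = integer(0), n_voting = integer(0),
               agreement_fraction = numeric(0))]
    return(out)
  }
  fam_size <- obs[, .(family_size = uniqueN(read_id)), by = family_id]

  key <- c("family_id", "chrom", "pos")
  cnt <- obs[, .(n = .N), by = c(key, "obs_base")]
  tot <- cnt[, .(n_voting = sum(n)), by = key]
  setorderv(cnt, c(key, "n"), order = c(1L, 1L, 1L, -1L))
  top <- cnt[cnt[, .I[1L], by = key]$V1][tot, on = key]
  top <- if (consensus_rule == "unanimous") top[n == n_voting]
         else top[2L * n > n_voting]
  if (nrow(top) == 0) return(des_consensus(obs[0], consensus_rule))

  meta <- obs[, .(ref_base = ref_base[1L], read_id = read_id[1L],
                  umi = umi[1L], fragment_start = fragment_start[1L],
                  fragment_end = fragment_end[1L],
                  fragment_strand = fragment_strand[1L],
                  dist_from_breakpoint = min(dist_from_breakpoint)),
              by = key]
  qual <- obs[top[, c(..key, "obs_base")], on = c(key, "obs_base"),
              nomatch = 0L][, .(base_quality = max(base_quality)), by = key]
  cons <- top[, c(..key, "obs_base", "n", "n_voting")][meta, on = key,
                                                       nomatch = 0L]
  cons <- qual[cons, on = key]
  cons <- fam_size[cons, on = "family_id"]
  cons[, `:=`(agreement_fraction = n / n_voting, n = NULL, mate = 1L)]
  setcolorder(cons, c("chrom", "pos", "ref_base", "obs_base", "base_quality",
                      "read_id", "mate", "umi", "fragment_start",
                      "fragment_end", "fragment_strand",
                      "dist_from_breakpoint", "family_id", "family_size",
                      "n_voting", "agreement_fraction"))
  cons[]
}

#' Quantify the effect of digital error suppression
#'
#' Relative reduction of each class rate after consensus collapsing:
#' `reduction = 1 - rate_des / rate_raw`, reported as a percentage.
#' Classes with a zero or missing raw rate are reported `NA`.
#'
#' @param profile_raw,profile_des `error_profile`s of the same sample
#'   before and after DES.
#' @return `data.table` with columns `class` (12 classes plus `"total"`),
#'   `rate_raw`, `rate_des`, `reduction_pct`.
#' @export
#' @examples
#' # a total rate falling from 0.0064% to 0.0044% is a 31.25% reduction
des_effect <- function(profile_raw, profile_des) {
  stopifnot(inherits(profile_raw, "error_profile"),
            inherits(profile_des, "error_profile"))
  if (!identical(profile_raw$sample_id, profile_des$sample_id))
    warning("profiles come from different samples: ",
            profile_raw$sample_id, " vs ", profile_des$sample_id)
  raw <- c(profile_raw$rates, total = profile_raw$total_rate)
  des <- c(profile_des$rates, total = profile_des$total_rate)
  red <- ifelse(!is.na(raw) & raw > 0, (1 - des / raw) * 100, NA_real_)
  data.table(class = c(SUBSTITUTION_CLASSES, "total"),
             rate_raw = as.numeric(raw), rate_des = as.numeric(des),
             reduction_pct = as.numeric(red))
}
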