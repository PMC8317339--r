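#' Load a target panel from BED
#'
#' Reads a 3+ column BED file, sorts and merges overlapping intervals, and
#' records the merged footprint in base pairs. Internal coordinates stay in
#' the GRanges 1-based closed convention; the BED input is 0-based
#' half-open as usual.
#'
#' @param path BED file path.
#' @return A [GenomicRanges::GRanges] of disjoint sorted intervals with a
#'   `total_bp` value in `metadata()`.
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("malformed BED '", path, "': ",
                                          conditionMessage(e)))
  if (length(gr) == 0) stop("panel file '", path, "' contains no intervals")
  gr <- GenomeInfoDb::sortSeqlevels(gr)
  gr <- GenomicRanges::reduce(GenomicRanges::sort(gr), ignore.strand = TRUE)
  S4Vectors::metadata(gr)$total_bp <- sum(GenomicRanges::width(gr))
  gr
}

#' Total footprint of a panel
#'
#' @param panel GRanges as returned by [load_panel()].
#' @return Total merged width in bp.
#' @export
panel_total_bp <- function(panel) {
  tb <- S4Vectors::metadata(panel)$total_bp
  if (is.null(tb)) sum(GenomicRanges::width(GenomicRanges::reduce(panel))) else tb
}

#' Assign a breakpoint distance to a 5-bp bin
#'
#' Distances 1..50 from the read's 5' end map to bins 1..10
#' (bin = ceiling(distance / 5)); larger distances fall outside the
#' breakpoint analysis and return `NA`.
#'
#' @param dist Integer vector of distances (>= 1).
#' @return Integer bin indices 1..10, or `NA` beyond 50 bp.
#' @export
#' @examples
#' fragment_bin(c(1, 5, 6, 50, 51))
fragment_bin <- function(dist) {
  if (any(dist < 1, na.rm = TRUE)) stop("breakpoint distance must be >= 1")
  b <- as.integer(ceiling(dist / 5))
  b[dist > 50L] <- NA_integer_
  b
}

#' Stream per-base observations from an alignment file
#'
#' Walks every primary, mapped, non-duplicate alignment overlapping the
#' panel and emits one row per aligned (CIGAR M/=/X) base inside the panel:
#' the genomic position, reference and observed base, Phred quality, UMI,
#' fragment coordinates, and the base's 1-based distance from its read's
#' 5' end in original sequencing orientation (`dist_from_breakpoint`) —
#' for a reverse-strand alignment the 5' end sits at the highest aligned
#' coordinate, so distances count downwards along the genome. Soft-clipped
#' and inserted bases are skipped; deletions/N gaps consume reference but
#' emit nothing.
#'
#' Fragment coordinates come from the proper pair's outer span (leftmost
#' start, leftmost start + |TLEN|); reads without a usable template span
#' fall back to their own aligned span. `fragment_strand` is the strand of
#' read 1, so the two strands of one original molecule stay distinct when
#' UMI families are keyed.
#'
#' @param bam_path Coordinate-sorted, indexed BAM.
#' @param panel GRanges from [load_panel()].
#' @param reference_path FASTA with an `.fai` index (one is created if
#'   missing), containing every panel chromosome.
#' @param umi_source `"tag"` (read a BAM tag, default) or `"readname"`
#'   (last `umi_delim`-separated field of the read name).
#' @param umi_tag Tag holding the UMI when `umi_source = "tag"`.
#' @param umi_delim Read-name delimiter when `umi_source = "readname"`.
#' @param missing_umi `"skip"` reads without a UMI or `"fail"`.
#' @param min_mapq Minimum mapping quality; MAPQ 0 alignments are always
#'   skipped.
#' @return `data.table` with columns `chrom`, `pos` (1-based), `ref_base`,
#'   `obs_base`, `base_quality`, `read_id`, `mate`, `umi`,
#'   `fragment_start`, `fragment_end` (1-based closed), `fragment_strand`,
#'   `dist_from_breakpoint`.
#' @export
stream_observations <- function(bam_path, panel, reference_path,
                                umi_source = c("tag", "readname"),
                                umi_tag = "RX", umi_delim = ":",
                                missing_umi = c("skip", "fail"),
                                min_mapq = 1L) {
  umi_source <- match.arg(umi_source)
  missing_umi <- match.arg(missing_umi)
  if (!file.exists(bam_path)) stop("BAM not found: ", bam_path)
  if (!file.exists(paste0(bam_path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam_path)))
    stop("BAM index (.bai) not found for ", bam_path)

  fa <- Rsamtools::FaFile(reference_path)
  if (!file.exists(paste0(reference_path, ".fai")))
    Rsamtools::indexFa(reference_path)
  fa_seqs <- Rsamtools::scanFaIndex(fa)
  missing_chr <- setdiff(as.character(GenomeInfoDb::seqnames(panel)),
                         as.character(GenomeInfoDb::seqnames(fa_seqs)))
  if (length(missing_chr))
    stop("panel contig(s) absent from reference: ",
         paste(missing_chr, collapse = ", "))

  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isDuplicate = FALSE)
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
            "seq", "qual", "mpos", "isize")
  param <- Rsamtools::ScanBamParam(
    flag = flags, what = what,
    tag = if (umi_source == "tag") umi_tag else character(),
    which = GenomicRanges::reduce(panel))
  chunks <- Rsamtools::scanBam(bam_path, param = param)

  # merge windows into one read set; a read overlapping two panel windows
  # is returned once per window, so dedupe at the read level first
  fields <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
              "seq", "qual", "mpos", "isize")
  cat_field <- function(lst) if (length(lst) == 1L) lst[[1L]] else do.call(c, lst)
  ch <- lapply(fields, function(f) cat_field(lapply(chunks, `[[`, f)))
  names(ch) <- fields
  n <- length(ch$pos)
  if (n == 0) return(empty_observations())
  umi <- if (umi_source == "tag") {
    u <- do.call(c, lapply(chunks, function(x) {
      v <- x$tag[[umi_tag]]
      if (is.null(v)) rep(NA_character_, length(x$pos)) else v
    }))
    u
  } else {
    parts <- strsplit(ch$qname, umi_delim, fixed = TRUE)
    vapply(parts, function(p) if (length(p) >= 2) p[length(p)] else NA_character_,
           character(1))
  }
  if (anyNA(umi) && missing_umi == "fail")
    stop("alignment without UMI (", umi_source, " rule): ",
         ch$qname[which(is.na(umi))[1]])
  keep <- !is.na(umi) &
    !is.na(ch$mapq) & ch$mapq >= max(1L, as.integer(min_mapq)) &
    !duplicated(paste(ch$qname, ch$flag))
  if (!all(keep)) {
    umi <- umi[keep]
    ch <- lapply(ch, function(x) x[keep])
    n <- sum(keep)
  }
  if (n == 0) return(empty_observations())
  obs <- expand_alignments(ch, umi, fa)
  if (nrow(obs) == 0) return(obs)
  # restrict to panel positions (reads can overhang interval edges)
  obs[in_panel(obs$chrom, obs$pos, panel)]
}

# vectorized membership of 1-based positions in a disjoint sorted GRanges
in_panel <- function(chrom, pos, panel) {
  panel <- GenomicRanges::reduce(GenomicRanges::sort(panel),
                                 ignore.strand = TRUE)
  res <- logical(length(pos))
  for (chr in unique(chrom)) {
    sel <- chrom == chr
    iv <- panel[as.character(GenomeInfoDb::seqnames(panel)) == chr]
    if (length(iv) == 0) next
    st <- GenomicRanges::start(iv); en <- GenomicRanges::end(iv)
    idx <- findInterval(pos[sel], st)
    res[sel] <- idx > 0 & pos[sel] <= en[pmax(idx, 1L)]
  }
  res
}

empty_observations <- function() {
  data.table(chrom = character(), pos = integer(), ref_base = character(),
             obs_base = character(), base_quality = integer(),
             read_id = character(), mate = integer(), umi = character(),
             fragment_start = integer(), fragment_end = integer(),
             fragment_strand = character(),
             dist_from_breakpoint = integer())
}

# Expand one scanBam chunk into per-base rows using the CIGAR layout.
expand_alignments <- function(ch, umi, fa) {
  n <- length(ch$pos)
  cig <- ch$cigar
  ops <- GenomicAlignments::explodeCigarOps(cig)
  lens <- GenomicAlignments::explodeCigarOpLengths(cig)
  # full SEQ length: query space includes soft-clipped bases
  qwidth <- GenomicAlignments::cigarWidthAlongQuerySpace(cig)
  is_rev <- bitwAnd(ch$flag, 16L) != 0L
  is_r2 <- bitwAnd(ch$flag, 128L) != 0L
  is_paired <- bitwAnd(ch$flag, 1L) != 0L

  # fragment outer span from TLEN when informative, else own span
  ref_w <- GenomicAlignments::cigarWidthAlongReferenceSpace(cig)
  own_start <- ch$pos
  own_end <- ch$pos + ref_w - 1L
  frag_start <- ifelse(is_paired & !is.na(ch$isize) & ch$isize != 0L,
                       pmin(own_start, ifelse(is.na(ch$mpos), own_start, ch$mpos)),
                       own_start)
  frag_end <- ifelse(is_paired & !is.na(ch$isize) & ch$isize != 0L,
                     frag_start + abs(ch$isize) - 1L,
                     own_end)
  # strand of read 1: own strand for R1, the opposite for a proper-pair R2
  r1_rev <- ifelse(is_r2, !is_rev, is_rev)

  # per-base (query position, reference position) layout per read:
  # vectorized fast path for plain nM CIGARs, explicit walk otherwise
  simple <- grepl("^[0-9]+M$", cig)
  long_parts <- list()
  if (any(simple)) {
    w <- qwidth[simple]
    row <- rep(which(simple), w)
    qpos <- sequence(w)
    long_parts$simple <- data.table(
      row = row, qpos = qpos,
      pos = rep(ch$pos[simple], w) + qpos - 1L)
  }
  for (i in which(!simple)) {
    o <- ops[[i]]; l <- lens[[i]]
    qpos <- integer(0); rpos <- integer(0)
    qcur <- 1L; rcur <- ch$pos[i]
    for (k in seq_along(o)) {
      op <- o[k]; lk <- l[k]
      if (op %in% c("M", "=", "X")) {
        qpos <- c(qpos, qcur:(qcur + lk - 1L))
        rpos <- c(rpos, rcur:(rcur + lk - 1L))
        qcur <- qcur + lk; rcur <- rcur + lk
      } else if (op %in% c("I", "S")) {
        qcur <- qcur + lk
      } else if (op %in% c("D", "N")) {
        rcur <- rcur + lk
      }  # hard clip consumes nothing in SEQ
    }
    if (length(qpos) == 0) next
    long_parts[[length(long_parts) + 1L]] <-
      data.table(row = i, qpos = qpos, pos = rpos)
  }
  long <- rbindlist(long_parts)
  if (nrow(long) == 0) return(empty_observations())
  setorder(long, row, qpos)
  i <- long$row
  dist <- long$qpos
  rv <- which(is_rev[i])
  dist[rv] <- qwidth[i[rv]] - long$qpos[rv] + 1L
  # flat base/quality lookup across all reads
  seq_all <- unlist(strsplit(as.character(ch$seq), "", fixed = TRUE),
                    use.names = FALSE)
  qual_all <- unlist(as(Biostrings::PhredQuality(ch$qual), "IntegerList"),
                     use.names = FALSE)
  off <- cumsum(qwidth) - qwidth  # flat offset of each read's first base
  flat <- off[i] + long$qpos
  chrom_by_read <- as.character(ch$rname)
  dt <- data.table(
    chrom = chrom_by_read[i],
    pos = long$pos,
    obs_base = seq_all[flat],
    base_quality = qual_all[flat],
    read_id = ch$qname[i],
    mate = 1L + as.integer(is_r2[i]),
    umi = umi[i],
    fragment_start = as.integer(frag_start[i]),
    fragment_end = as.integer(frag_end[i]),
    fragment_strand = c("+", "-")[1L + as.integer(r1_rev[i])],
    dist_from_breakpoint = dist)
  dt <- dt[obs_base %chin% BASES]  # drop N / ambiguity codes
  # reference bases in one ranged lookup over the distinct positions
  uniq <- unique(dt[, .(chrom, pos)])
  refseq <- Biostrings::getSeq(
    fa, GenomicRanges::GRanges(uniq$chrom, IRanges::IRanges(uniq$pos, uniq$pos)))
  uniq[, ref_base := as.character(refseq)]
  dt <- uniq[dt, on = c("chrom", "pos")]
  dt <- dt[ref_base %chin% BASES]
  setcolorder(dt, c("chrom", "pos", "ref_base", "obs_base", "base_quality",
                    "read_id", "mate", "umi", "fragment_start",
                    "fragment_end", "fragment_strand",
                    "dist_from_breakpoint"))
  dt[]
}
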