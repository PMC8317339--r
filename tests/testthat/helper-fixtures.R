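library(data.table)

# write a tiny reference FASTA and return its path
write_test_reference <- function(seqs, dir = tempfile("ref")) {
  dir.create(dir, showWarnings = FALSE)
  path <- file.path(dir, "ref.fa")
  xs <- Biostrings::DNAStringSet(seqs)
  names(xs) <- names(seqs)
  Biostrings::writeXStringSet(xs, path)
  Rsamtools::indexFa(path)
  path
}

# build an indexed BAM from hand-written alignment rows
# rows: data.frame with qname, flag, rname, pos, cigar, seq, qual (phred
# ints collapsed), pnext, tlen, and optional rx (UMI)
write_test_bam <- function(rows, seqlens, dir = tempfile("bam")) {
  dir.create(dir, showWarnings = FALSE)
  rows <- as.data.table(rows)
  if (!"mapq" %in% names(rows)) rows[, mapq := 60L]
  if (!"rnext" %in% names(rows)) rows[, rnext := "="]
  if (!"rx" %in% names(rows)) rows[, rx := "ACGT"]
  rows[bitwAnd(flag, 1L) == 0L, `:=`(rnext = "*", pnext = 0L)]
  sam <- file.path(dir, "t.sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", names(seqlens), "\tLN:", seqlens))
  setorder(rows, pos)
  body <- rows[, paste(qname, flag, rname, pos, mapq, cigar, rnext, pnext,
                       tlen, seq, qual, paste0("RX:Z:", rx), sep = "\t")]
  writeLines(c(hdr, body), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "t"), overwrite = TRUE,
                          indexDestination = TRUE)
  bam
}

qstr <- function(q, n) paste(rep(intToUtf8(q + 33L), n), collapse = "")

# a small BED file
write_test_bed <- function(df, path = tempfile(fileext = ".bed")) {
  writeLines(apply(df, 1, paste, collapse = "\t"), path)
  path
}

# naive per-site tally oracle for build_site_counts
naive_site_counts <- function(obs, min_q) {
  obs <- as.data.table(obs)
  keep <- obs[base_quality >= min_q & obs_base %in% c("A", "C", "G", "T")]
  out <- list()
  for (key in unique(paste(keep$chrom, keep$pos))) {
    sub <- keep[paste(chrom, pos) == key]
    out[[key]] <- data.table(
      chrom = sub$chrom[1], pos = sub$pos[1], ref_base = sub$ref_base[1],
      depth = nrow(sub),
      A = sum(sub$obs_base == "A"), C = sum(sub$obs_base == "C"),
      G = sum(sub$obs_base == "G"), T = sum(sub$obs_base == "T"))
  }
  res <- rbindlist(out)
  setkey(res, chrom, pos)
  res[]
}

# random observation table generator for oracle tests
random_observations <- function(n, n_pos = 20, seed = 1) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  pos <- sample.int(n_pos, n, replace = TRUE)
  ref <- sample(bases, n_pos, replace = TRUE)
  data.table(
    chrom = "chr1", pos = pos, ref_base = ref[pos],
    obs_base = sample(c(bases, "N"), n, replace = TRUE,
                      prob = c(rep(0.24, 4), 0.04)),
    base_quality = sample(c(15L, 25L, 30L, 37L), n, replace = TRUE),
    read_id = paste0("r", seq_len(n)), mate = 1L,
    umi = "AAAA", fragment_start = 1L, fragment_end = 200L,
    fragment_strand = "+",
    dist_from_breakpoint = sample.int(120L, n, replace = TRUE))
}

# brute-force plurality-with-strict-majority consensus oracle
oracle_consensus <- function(bases) {
  tb <- table(bases)
  top <- names(tb)[which.max(tb)]
  if (max(tb) * 2 > length(bases)) top else NA_character_
}
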