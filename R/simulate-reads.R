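QUAL33 <- function(q) intToUtf8(q + 33L, multiple = TRUE)

#' Simulate aligned reads with UMI families and a truth ledger
#'
#' Emits one coordinate-sorted indexed BAM per sample, plus the shared
#' reference FASTA (panel plus flanks) and panel BED, emulating the damage
#' topology of a UMI-tagged library:
#'
#' * each template molecule (fragment) receives germline alleles, then
#'   molecule-level damage per class (`rates_cfdna` / `rates_gdna`, with
#'   the end-effect multiplier on the first `first_k_bp` of each fragment
#'   end for gDNA-like samples), then first-cycle PCR errors
#'   (`pcr_error_rate`) — all of these are shared by every read of the
#'   molecule's UMI family, so digital error suppression cannot remove
#'   them;
#' * the molecule is then expanded to a zero-truncated-Poisson number of
#'   read pairs (mean `umi_mean_progeny`), and each read independently
#'   receives sequencer errors (`seq_error_rate`), which are private to
#'   one read and therefore removable wherever the family has redundancy.
#'
#' Every planted non-reference base is recorded in the ledger with its
#' category (`germline`, `damage`, `pcr`, `seq`).
#'
#' @param config A [sim_config()] with `mode = "reads"`.
#' @param dir Output directory (created if needed).
#' @return Manifest list: `dir`, `reference`, `panel_bed`, `samples`
#'   (sample sheet plus `bam` paths), `ledger` (germline table with
#'   genomic coordinates, per-sample `mol_events`, `seq_events`,
#'   `families`), and the `config`.
#' @export
simulate_reads <- function(config, dir = tempfile("simreads")) {
  stopifnot(inherits(config, "sim_config"))
  if (config$mode != "reads") stop("config mode must be 'reads'")
  set.seed(config$seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  margin <- max(config$fragment_length_cfdna, config$fragment_length_gdna)
  ref_len <- config$panel_bp + 2L * margin
  ref_chars <- sample(BASES, ref_len, replace = TRUE)
  truth <- sim_panel_truth(config)
  # panel occupies [margin+1, margin+panel_bp] on the synthetic contig
  ref_chars[margin + seq_len(config$panel_bp)] <- truth$ref
  ref_str <- paste(ref_chars, collapse = "")
  germline <- copy(truth$germline)
  if (nrow(germline) > 0) germline[, pos := pos + margin]

  fa_path <- file.path(dir, "reference.fa")
  seqs <- Biostrings::DNAStringSet(ref_str)
  names(seqs) <- config$chrom
  Biostrings::writeXStringSet(seqs, fa_path, width = 70L)
  Rsamtools::indexFa(fa_path)
  bed_path <- file.path(dir, "panel.bed")
  writeLines(paste(config$chrom, margin, margin + config$panel_bp,
                   sep = "\t"), bed_path)

  meta <- sim_sample_meta(config)
  bam_paths <- character(nrow(meta))
  mol_events <- seq_events <- families <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    res <- sim_sample_reads(config, meta$sample_type[i], meta$sample_id[i],
                            ref_chars, ref_str, margin, germline, dir)
    bam_paths[i] <- res$bam
    mol_events[[i]] <- res$mol_events
    seq_events[[i]] <- res$seq_events
    families[[i]] <- res$families
  }
  samples <- copy(meta)[, bam := bam_paths]
  list(dir = dir, reference = fa_path, panel_bed = bed_path,
       samples = samples,
       ledger = list(germline = germline,
                     mol_events = rbindlist(mol_events),
                     seq_events = rbindlist(seq_events),
                     families = rbindlist(families),
                     seed = config$seed),
       config = config)
}

sim_sample_reads <- function(config, sample_type, sample_id, ref_chars,
                             ref_str, margin, germline, dir) {
  L <- if (sample_type == "cfDNA") config$fragment_length_cfdna
       else config$fragment_length_gdna
  rates <- if (sample_type == "cfDNA") config$rates_cfdna
           else config$rates_gdna
  end_eff <- if (sample_type == "gDNA") config$end_effect else NULL
  rl <- config$read_length
  nfr <- config$n_fragments[[sample_type]]
  panel_start <- margin + 1L
  panel_end <- margin + config$panel_bp

  # template molecules: uniform starts covering the panel, random 4-bp UMI
  start <- panel_start - L + 1L + sample.int(config$panel_bp + L - 1L, nfr,
                                             replace = TRUE) - 1L
  end <- start + L - 1L
  umi <- do.call(paste0, as.data.frame(
    matrix(sample(BASES, 4L * nfr, replace = TRUE), nfr, 4L)))
  famsize <- rztpois(nfr, config$umi_mean_progeny)
  r1_rev <- runif(nfr) < 0.5

  mol_str <- substring(ref_str, start, end)

  ev <- list()
  # germline alleles: molecule carries the alt with probability AF
  if (nrow(germline) > 0) {
    for (g in seq_len(nrow(germline))) {
      gp <- germline$pos[g]
      cover <- which(start <= gp & end >= gp)
      carrier <- cover[runif(length(cover)) < germline$af[g]]
      if (length(carrier))
        ev[[length(ev) + 1L]] <- data.table(
          frag = carrier, offset = gp - start[carrier] + 1L, pos = gp,
          ref = germline$ref[g], alt = germline$alt[g],
          category = "germline")
    }
  }
  germ_ev <- rbindlist(ev)

  # molecule-level damage: exact binomial event counts per class, with the
  # fragment-end multiplier handled as a separate stratum
  slot_frag <- rep(seq_len(nfr), each = L)
  slot_off <- rep(seq_len(L), times = nfr)
  slot_base <- ref_chars[rep(start, each = L) + slot_off - 1L]
  if (nrow(germ_ev) > 0) {
    gi <- (germ_ev$frag - 1L) * L + germ_ev$offset
    slot_base[gi] <- germ_ev$alt
  }
  is_end <- if (is.null(end_eff)) rep(FALSE, length(slot_off))
            else slot_off <= end_eff$first_k_bp |
                 slot_off > L - end_eff$first_k_bp
  dmg <- list()
  for (cls in SUBSTITUTION_CLASSES) {
    r <- rates[cls]
    mult <- if (!is.null(end_eff) && cls == end_eff$class)
      end_eff$multiplier else 1
    if (r <= 0) next
    for (stratum in list(list(sel = !is_end, rate = r),
                         list(sel = is_end, rate = r * mult))) {
      idx <- which(stratum$sel & slot_base == class_ref(cls))
      if (!length(idx) || stratum$rate <= 0) next
      k <- rbinom(1L, length(idx), stratum$rate)
      if (k == 0) next
      hit <- if (k >= length(idx)) idx else sample(idx, k)
      dmg[[length(dmg) + 1L]] <- data.table(
        frag = slot_frag[hit], offset = slot_off[hit],
        pos = start[slot_frag[hit]] + slot_off[hit] - 1L,
        ref = class_ref(cls), alt = class_alt(cls), category = "damage")
    }
  }
  dmg <- rbindlist(dmg)
  # first-cycle PCR errors: uniform over molecule bases, random alternate
  pcr <- data.table()
  if (config$pcr_error_rate > 0) {
    k <- rbinom(1L, nfr * L, config$pcr_error_rate)
    if (k > 0) {
      hit <- sample.int(nfr * L, k)
      cur <- slot_base[hit]
      alt <- vapply(cur, function(b) sample(setdiff(BASES, b), 1L),
                    character(1))
      pcr <- data.table(frag = slot_frag[hit], offset = slot_off[hit],
                        pos = start[slot_frag[hit]] + slot_off[hit] - 1L,
                        ref = cur, alt = alt, category = "pcr")
    }
  }
  mol_ev <- rbindlist(list(germ_ev, dmg, pcr), fill = TRUE)
  if (nrow(mol_ev) > 0) {
    # precedence by category order above; drop later events on a used slot
    mol_ev <- unique(mol_ev, by = c("frag", "offset"))
    for (j in seq_len(nrow(mol_ev)))
      substr(mol_str[mol_ev$frag[j]], mol_ev$offset[j],
             mol_ev$offset[j]) <- mol_ev$alt[j]
  }

  # progeny expansion: one R1/R2 pair per family member
  pair_frag <- rep(seq_len(nfr), famsize)
  pair_idx <- sequence(famsize)
  npair <- length(pair_frag)
  qname <- paste0(sample_id, ":f", pair_frag, ":", pair_idx)
  frev <- r1_rev[pair_frag]
  left_pos <- start[pair_frag]
  right_pos <- end[pair_frag] - rl + 1L
  # R1 sits at the 5' breakpoint of its strand; R2 at the other end
  r1_pos <- ifelse(frev, right_pos, left_pos)
  r2_pos <- ifelse(frev, left_pos, right_pos)
  r1_off <- ifelse(frev, L - rl + 1L, 1L)
  r2_off <- ifelse(frev, 1L, L - rl + 1L)
  reads <- data.table(
    qname = rep(qname, 2L),
    mate = rep(c(1L, 2L), each = npair),
    frag = rep(pair_frag, 2L),
    flag = c(ifelse(frev, 83L, 99L), ifelse(frev, 163L, 147L)),
    pos = c(r1_pos, r2_pos),
    pnext = c(r2_pos, r1_pos),
    tlen = c(ifelse(frev, -L, L), ifelse(frev, L, -L)),
    off = c(r1_off, r2_off))
  reads[, seq := substring(mol_str[frag], off, off + rl - 1L)]

  # per-read sequencer errors (private to one read)
  seq_ev <- data.table()
  if (config$seq_error_rate > 0) {
    nread <- nrow(reads)
    k <- rbinom(1L, nread * rl, config$seq_error_rate)
    if (k > 0) {
      hit <- sample.int(nread * rl, k)
      ri <- (hit - 1L) %/% rl + 1L
      off <- (hit - 1L) %% rl + 1L
      seqv <- reads$seq
      cur <- substring(seqv[ri], off, off)
      alt <- vapply(cur, function(b) sample(setdiff(BASES, b), 1L),
                    character(1))
      for (j in seq_along(ri))
        substr(seqv[ri[j]], off[j], off[j]) <- alt[j]
      reads[, seq := seqv]
      seq_ev <- data.table(sample_id = sample_id, qname = reads$qname[ri],
                           mate = reads$mate[ri],
                           pos = reads$pos[ri] + off - 1L,
                           ref = cur, alt = alt, category = "seq")
    }
  }

  # Phred strings from a fixed pool of draws from the quality distribution
  pool_n <- 499L
  pool <- vapply(seq_len(pool_n), function(i)
    paste(QUAL33(sample(config$quality_levels, rl, replace = TRUE,
                        prob = config$quality_probs)), collapse = ""),
    character(1))
  reads[, qual := pool[sample.int(pool_n, .N, replace = TRUE)]]

  sam <- reads[, .(qname, flag, rname = config$chrom, pos,
                   mapq = 60L, cigar = paste0(rl, "M"), rnext = "=",
                   pnext, tlen, seq, qual,
                   rx = paste0("RX:Z:", umi[frag]))]
  setorder(sam, pos, qname)
  sam_path <- file.path(dir, paste0(sample_id, ".sam"))
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              paste0("@SQ\tSN:", config$chrom, "\tLN:", nchar(ref_str)))
  writeLines(header, sam_path)
  fwrite(sam, sam_path, sep = "\t", col.names = FALSE, append = TRUE,
         quote = FALSE)
  bam_path <- Rsamtools::asBam(sam_path,
                               file.path(dir, sample_id),
                               overwrite = TRUE, indexDestination = TRUE)
  unlink(sam_path)

  if (nrow(mol_ev) > 0) mol_ev[, `:=`(sample_id = sample_id, offset = NULL)]
  list(bam = bam_path,
       mol_events = mol_ev,
       seq_events = seq_ev,
       families = data.table(sample_id = sample_id, frag = seq_len(nfr),
                             umi = umi, chrom = config$chrom,
                             fragment_start = start, fragment_end = end,
                             fragment_strand = ifelse(r1_rev, "-", "+"),
                             family_size = famsize))
}
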