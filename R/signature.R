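#' The 96 trinucleotide mutation channels
#'
#' Standard single-base-substitution channels: 6 collapsed (pyrimidine
#' reference) classes x 16 flanking-base contexts, labelled like
#' `"A[C>T]G"`.
#'
#' @return Character vector of 96 channel labels in the conventional
#'   order (C>A, C>G, C>T, T>A, T>C, T>G; contexts alphabetical).
#' @export
trinuc_channels <- function() {
  pyr <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(0)
  for (cls in pyr)
    for (up in BASES)
      for (dn in BASES)
        out <- c(out, paste0(up, "[", cls, "]", dn))
  out
}

#' Build a 96-channel trinucleotide error spectrum
#'
#' Orients every error onto the pyrimidine strand (a `G>A` error in
#' context `TGA` is counted as `C>T` in `TCA`: the reverse complement) and
#' tallies counts per channel. Errors whose +/-1 bp context is unavailable
#' (contig edge, non-ACGT flank) are dropped and counted in
#' `n_dropped`.
#'
#' @param errors `data.table` with columns `chrom`, `pos` (1-based),
#'   `ref_base`, `alt_base`, and optionally `count` (default 1 per row).
#' @param reference_path FASTA path (indexed or indexable).
#' @return List with `counts` (named vector over [trinuc_channels()]),
#'   `fractions` (counts / total, `NA` if total 0), and `n_dropped`.
#' @export
trinuc_spectrum <- function(errors, reference_path) {
  errors <- as.data.table(errors)
  stopifnot(all(c("chrom", "pos", "ref_base", "alt_base") %in% names(errors)))
  if (!"count" %in% names(errors)) errors[, count := 1L]
  channels <- trinuc_channels()
  counts <- setNames(numeric(96), channels)
  dropped <- 0L
  if (nrow(errors) > 0) {
    fa <- Rsamtools::FaFile(reference_path)
    if (!file.exists(paste0(reference_path, ".fai")))
      Rsamtools::indexFa(reference_path)
    lens <- Rsamtools::scanFaIndex(fa)
    len_map <- setNames(GenomicRanges::width(lens),
                        as.character(GenomeInfoDb::seqnames(lens)))
    edge <- errors$pos <= 1L | errors$pos >= len_map[errors$chrom]
    dropped <- sum(errors$count[edge])
    ok <- errors[!edge]
    if (nrow(ok) > 0) {
      ctx <- Biostrings::getSeq(
        fa, GenomicRanges::GRanges(ok$chrom,
                                   IRanges::IRanges(ok$pos - 1L, ok$pos + 1L)))
      ctx <- as.character(ctx)
      bad <- !grepl("^[ACGT]{3}$", ctx) |
        substr(ctx, 2, 2) != ok$ref_base | !(ok$alt_base %in% BASES)
      dropped <- dropped + sum(ok$count[bad])
      ok <- ok[!bad]; ctx <- ctx[!bad]
      if (nrow(ok) > 0) {
        flip <- ok$ref_base %in% c("A", "G")
        rc <- function(s) chartr("ACGT", "TGCA", sapply(strsplit(s, ""), function(x)
          paste(rev(x), collapse = "")))
        ctx[flip] <- rc(ctx[flip])
        ref <- ifelse(flip, BASE_COMPLEMENT[ok$ref_base], ok$ref_base)
        alt <- ifelse(flip, BASE_COMPLEMENT[ok$alt_base], ok$alt_base)
        chan <- paste0(substr(ctx, 1, 1), "[", ref, ">", alt, "]",
                       substr(ctx, 3, 3))
        agg <- data.table(chan = chan, count = ok$count)[, .(n = sum(count)),
                                                         by = chan]
        counts[agg$chan] <- agg$n
      }
    }
  }
  total <- sum(counts)
  list(counts = counts,
       fractions = if (total > 0) counts / total else rep(NA_real_, 96),
       n_dropped = dropped)
}

# Lawson-Hanson non-negative least squares (active set); A is m x k.
nnls_fit <- function(A, b, tol = 1e-10, max_iter = 300L) {
  k <- ncol(A)
  x <- numeric(k)
  passive <- logical(k)
  w <- crossprod(A, b - A %*% x)
  it <- 0L
  while (any(!passive & w > tol) && it < max_iter) {
    it <- it + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      s <- numeric(k)
      s[passive] <- qr.solve(A[, passive, drop = FALSE], b)
      if (all(s[passive] > tol)) { x <- s; break }
      neg <- passive & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive <- passive & x > tol
      x[!passive] <- 0
    }
    w <- crossprod(A, b - A %*% x)
  }
  x
}

#' Refit a spectrum against a signature matrix
#'
#' Non-negative least-squares decomposition of an observed 96-channel
#' spectrum onto user-supplied signatures (e.g. a COSMIC SBS subset):
#' minimizes `||S w - spectrum||^2` subject to `w >= 0`, then reports each
#' signature's share of the fitted total.
#'
#' @param spectrum Result of [trinuc_spectrum()], or a numeric vector of
#'   96 counts/fractions.
#' @param signatures 96 x k matrix with non-negative columns summing to 1;
#'   rownames, when present, must be the channel labels.
#' @return List with `weights` (raw non-negative coefficients),
#'   `fractions` (weights normalized to sum 1; the reported contribution
#'   percentages), and `residual` (relative L2 residual of the fit).
#' @export
signature_refit <- function(spectrum, signatures) {
  b <- if (is.list(spectrum)) spectrum$counts else spectrum
  if (length(b) != 96) stop("spectrum must have 96 channels")
  signatures <- as.matrix(signatures)
  if (nrow(signatures) != 96)
    stop("signature matrix must have 96 rows")
  if (any(signatures < 0))
    stop("signature matrix must be non-negative")
  csum <- colSums(signatures)
  if (any(abs(csum - 1) > 1e-6))
    stop("signature columns must each sum to 1")
  if (!is.null(rownames(signatures)) && !is.null(names(b)))
    signatures <- signatures[names(b), , drop = FALSE]
  w <- nnls_fit(signatures, as.numeric(b))
  names(w) <- colnames(signatures)
  frac <- if (sum(w) > 0) w / sum(w) else rep(NA_real_, length(w))
  fitted <- as.numeric(signatures %*% w)
  res <- if (sum(b^2) > 0) sqrt(sum((b - fitted)^2) / sum(b^2)) else 0
  list(weights = w, fractions = frac, residual = res)
}
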