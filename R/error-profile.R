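#' Construct an error profile from class counts and eligible bases
#'
#' The central summary of a sample's background errors. Rates are
#' opportunity-normalized by default: the rate of class `r>a` is the number
#' of `a` bases observed over eligible positions whose reference is `r`,
#' divided by the total sequenced bases over those reference-`r` positions.
#' `denominator = "total"` instead divides every class count by the total
#' sequenced bases over all eligible positions.
#'
#' @param sample_id Sample label.
#' @param error_counts Named integer vector over the 12 directional classes
#'   (missing classes are taken as 0).
#' @param eligible_bases Named numeric vector over the reference bases
#'   A/C/G/T: total retained sequenced bases at eligible positions with
#'   that reference base.
#' @param eligible_positions Optional named vector: number of eligible
#'   positions per reference base (bookkeeping only).
#' @param denominator `"opportunity"` (default) or `"total"`.
#' @return An `error_profile` object with elements `rates` (12),
#'   `collapsed_rates` (6), `total_rate`, `error_counts`, `eligible_bases`.
#'   Rates are `NA` for classes whose denominator is zero.
#' @export
error_profile <- function(sample_id, error_counts, eligible_bases,
                          eligible_positions = NULL,
                          denominator = c("opportunity", "total")) {
  denominator <- match.arg(denominator)
  counts <- setNames(numeric(12), SUBSTITUTION_CLASSES)
  if (length(error_counts)) {
    check_class(names(error_counts))
    counts[names(error_counts)] <- as.numeric(error_counts)
  }
  if (any(counts < 0)) stop("error counts must be non-negative")
  elig <- setNames(numeric(4), BASES)
  if (length(eligible_bases)) {
    stopifnot(all(names(eligible_bases) %in% BASES))
    elig[names(eligible_bases)] <- as.numeric(eligible_bases)
  }
  denom <- if (denominator == "opportunity") elig[class_ref(SUBSTITUTION_CLASSES)]
           else rep(sum(elig), 12)
  rates <- ifelse(denom > 0, counts / denom, NA_real_)
  names(rates) <- SUBSTITUTION_CLASSES

  coll_counts <- vapply(COLLAPSED_CLASSES, function(cc)
    sum(counts[collapsed_members(cc)]), numeric(1))
  coll_denom <- vapply(COLLAPSED_CLASSES, function(cc) {
    refs <- unique(class_ref(collapsed_members(cc)))  # the two paired ref bases
    if (denominator == "opportunity") sum(elig[refs]) else sum(elig)
  }, numeric(1))
  coll <- setNames(ifelse(coll_denom > 0, coll_counts / coll_denom, NA_real_),
                   COLLAPSED_CLASSES)

  total <- if (sum(elig) > 0) sum(counts) / sum(elig) else NA_real_

  structure(
    list(sample_id = sample_id,
         rates = rates,
         collapsed_rates = coll,
         total_rate = total,
         error_counts = counts,
         eligible_bases = elig,
         eligible_positions = eligible_positions,
         denominator = denominator),
    class = "error_profile")
}

#' @export
print.error_profile <- function(x, ...) {
  cat("error_profile for sample '", x$sample_id, "'\n", sep = "")
  cat(sprintf("  total rate: %.3g  (%.3g errors per 1e5 bases; %s-normalized)\n",
              x$total_rate, x$total_rate * 1e5, x$denominator))
  df <- data.frame(class = SUBSTITUTION_CLASSES,
                   count = x$error_counts,
                   rate = signif(x$rates, 4),
                   row.names = NULL)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Tabulate an error profile
#'
#' @param profile An `error_profile`.
#' @return `data.table` with one row per directional class, per collapsed
#'   class, and a `total` row; columns `sample_id`, `scope`, `class`,
#'   `count`, `eligible_bases`, `rate`.
#' @export
profile_table <- function(profile) {
  stopifnot(inherits(profile, "error_profile"))
  denom12 <- if (profile$denominator == "opportunity")
    profile$eligible_bases[class_ref(SUBSTITUTION_CLASSES)]
  else rep(sum(profile$eligible_bases), 12)
  coll <- collapse_class(SUBSTITUTION_CLASSES)
  denom6 <- vapply(COLLAPSED_CLASSES, function(cc) {
    refs <- unique(class_ref(collapsed_members(cc)))
    if (profile$denominator == "opportunity") sum(profile$eligible_bases[refs])
    else sum(profile$eligible_bases)
  }, numeric(1))
  rbindlist(list(
    data.table(sample_id = profile$sample_id, scope = "directional",
               class = SUBSTITUTION_CLASSES,
               count = as.numeric(profile$error_counts),
               eligible_bases = as.numeric(denom12),
               rate = as.numeric(profile$rates)),
    data.table(sample_id = profile$sample_id, scope = "collapsed",
               class = COLLAPSED_CLASSES,
               count = as.numeric(tapply(profile$error_counts, coll, sum)[COLLAPSED_CLASSES]),
               eligible_bases = as.numeric(denom6[COLLAPSED_CLASSES]),
               rate = as.numeric(profile$collapsed_rates)),
    data.table(sample_id = profile$sample_id, scope = "total",
               class = "total",
               count = sum(profile$error_counts),
               eligible_bases = sum(profile$eligible_bases),
               rate = profile$total_rate)))
}

#' Write / read an error profile as TSV plus JSON sidecar
#'
#' The TSV holds the 12 + 6 + 1 rate rows; the sidecar (`<path>.json`)
#' records the sample, the normalization mode, and the exact counts and
#' denominators so that re-reading reproduces the profile bit-identically.
#'
#' @param profile An `error_profile`.
#' @param path Output TSV path.
#' @param extra Optional named list merged into the sidecar metadata
#'   (e.g. the filter thresholds used).
#' @return `path`, invisibly.
#' @export
write_error_profile <- function(profile, path, extra = NULL) {
  fwrite(profile_table(profile), path, sep = "\t")
  meta <- list(sample_id = profile$sample_id,
               denominator = profile$denominator,
               error_counts = as.list(profile$error_counts),
               eligible_bases = as.list(profile$eligible_bases))
  if (!is.null(profile$eligible_positions))
    meta$eligible_positions <- as.list(profile$eligible_positions)
  if (!is.null(extra)) meta <- c(meta, extra)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_error_profile
#' @export
read_error_profile <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  ep <- unlist(meta$eligible_positions)
  error_profile(sample_id = meta$sample_id,
                error_counts = unlist(meta$error_counts),
                eligible_bases = unlist(meta$eligible_bases),
                eligible_positions = if (length(ep)) ep else NULL,
                denominator = meta$denominator)
}

#' Construct a fragment-breakpoint bin profile
#'
#' Error rates per substitution class in ten 5-bp bins of distance from the
#' read's 5' end (a true fragment breakpoint): bin `b` covers distances
#' `5(b-1)+1 .. 5b`, so bins 1..10 span the first 50 sequenced bases.
#'
#' @param sample_id Sample label.
#' @param bin_counts 10 x 12 matrix (bins x directional classes) of error
#'   counts.
#' @param bin_eligible_bases 10 x 4 matrix (bins x reference base) of
#'   retained sequenced bases.
#' @return A `fragment_bin_profile` with a 10 x 12 `bin_rates` matrix.
#' @export
fragment_bin_profile_obj <- function(sample_id, bin_counts, bin_eligible_bases) {
  stopifnot(identical(dim(bin_counts), c(10L, 12L)),
            identical(dim(bin_eligible_bases), c(10L, 4L)))
  colnames(bin_counts) <- SUBSTITUTION_CLASSES
  colnames(bin_eligible_bases) <- BASES
  rownames(bin_counts) <- rownames(bin_eligible_bases) <- paste0("bin", 1:10)
  denom <- bin_eligible_bases[, class_ref(SUBSTITUTION_CLASSES)]
  rates <- ifelse(denom > 0, bin_counts / denom, NA_real_)
  dimnames(rates) <- dimnames(bin_counts)
  structure(list(sample_id = sample_id,
                 bin_rates = rates,
                 bin_counts = bin_counts,
                 bin_eligible_bases = bin_eligible_bases),
            class = "fragment_bin_profile")
}

#' @export
print.fragment_bin_profile <- function(x, ...) {
  cat("fragment_bin_profile for sample '", x$sample_id,
      "' (rates x 1e5):\n", sep = "")
  print(round(x$bin_rates * 1e5, 2))
  invisible(x)
}

#' Write a fragment-bin profile as a long TSV
#'
#' @param profile A `fragment_bin_profile`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_bin_profile <- function(profile, path) {
  dt <- CJ(bin = 1:10, class = SUBSTITUTION_CLASSES, sorted = FALSE)
  dt[, `:=`(sample_id = profile$sample_id,
            count = as.vector(t(profile$bin_counts)),
            eligible_bases = as.vector(t(
              profile$bin_eligible_bases[, class_ref(SUBSTITUTION_CLASSES)])),
            rate = as.vector(t(profile$bin_rates)))]
  setcolorder(dt, c("sample_id", "bin", "class"))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}
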