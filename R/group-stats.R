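# Welch two-sample t-test on raw vectors; returns t, df, p (two-sided).
# Zero-variance handling follows the package-wide rule: both groups
# constant and equal -> p = 1; constant but different -> p = 0 sentinel.
welch_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                                    degenerate = TRUE))
  vx <- var(x); vy <- var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = nx + ny - 2, p = 1, degenerate = TRUE))
    return(list(t = Inf * sign(mean(x) - mean(y)), df = nx + ny - 2, p = 0,
                degenerate = TRUE))
  }
  se2 <- vx / nx + vy / ny
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df), degenerate = FALSE)
}

#' Compare class-wise error rates between two sample groups
#'
#' Welch (unequal-variance) two-sample t-test on the per-sample rates of
#' each substitution class, with Bonferroni correction across the class
#' tests; the total rate is tested separately and not included in the
#' correction.
#'
#' @param profiles Named list of [error_profile()]s.
#' @param groups Named character/factor vector (names = sample ids) with
#'   exactly two levels, e.g. `"cfDNA"` / `"gDNA"`.
#' @param alpha Significance level on the adjusted p-values (default
#'   0.01).
#' @param collapsed Test the 6 strand-collapsed classes instead of the 12
#'   directional ones.
#' @return List with `classes` (`data.table`: class, group means/SDs, t,
#'   p, adjusted p, significant flag, direction) and `total` (one-row
#'   `data.table` for the total rate, uncorrected).
#' @export
compare_class_rates <- function(profiles, groups, alpha = 0.01,
                                collapsed = FALSE) {
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2)
  g1 <- levels(groups)[1]; g2 <- levels(groups)[2]
  ids1 <- names(groups)[groups == g1]
  ids2 <- names(groups)[groups == g2]
  if (length(ids1) < 2 || length(ids2) < 2)
    stop("each group needs at least 2 replicate samples")
  stopifnot(all(c(ids1, ids2) %in% names(profiles)))
  classes <- if (collapsed) COLLAPSED_CLASSES else SUBSTITUTION_CLASSES
  getr <- function(id, cls) {
    p <- profiles[[id]]
    if (collapsed) p$collapsed_rates[cls] else p$rates[cls]
  }
  rows <- lapply(classes, function(cls) {
    x <- vapply(ids1, getr, numeric(1), cls = cls)
    y <- vapply(ids2, getr, numeric(1), cls = cls)
    wt <- welch_test(x, y)
    data.table(class = cls,
               mean_1 = mean(x), sd_1 = sd(x),
               mean_2 = mean(y), sd_2 = sd(y),
               t = wt$t, p = wt$p)
  })
  res <- rbindlist(rows)
  setnames(res, c("mean_1", "sd_1", "mean_2", "sd_2"),
           c(paste0("mean_", g1), paste0("sd_", g1),
             paste0("mean_", g2), paste0("sd_", g2)))
  res[, p_adj := pmin(1, p * length(classes))]
  res[, significant := !is.na(p_adj) & p_adj < alpha]
  res[, higher_group := ifelse(t > 0, g1, ifelse(t < 0, g2, NA_character_))]

  tx <- vapply(ids1, function(id) profiles[[id]]$total_rate, numeric(1))
  ty <- vapply(ids2, function(id) profiles[[id]]$total_rate, numeric(1))
  wt <- welch_test(tx, ty)
  total <- data.table(class = "total", mean_1 = mean(tx), sd_1 = sd(tx),
                      mean_2 = mean(ty), sd_2 = sd(ty), t = wt$t, p = wt$p,
                      p_adj = wt$p, significant = !is.na(wt$p) & wt$p < alpha,
                      higher_group = ifelse(wt$t > 0, g1,
                                            ifelse(wt$t < 0, g2, NA_character_)))
  setnames(total, c("mean_1", "sd_1", "mean_2", "sd_2"),
           c(paste0("mean_", g1), paste0("sd_", g1),
             paste0("mean_", g2), paste0("sd_", g2)))
  list(classes = res, total = total,
       groups = c(g1, g2), alpha = alpha, collapsed = collapsed)
}

#' Per-position group comparison of error rates
#'
#' Welch t-test at every (position, class) with per-sample rates from a
#' [position_error_table()]. Multiple testing is corrected within each
#' reference-base family by default (tests are enumerated per source base,
#' as A>N / C>N / G>N / T>N counts). Positions where both groups have zero
#' variance and equal means are untestable (p = 1 when equal; a constant
#' non-zero difference is flagged with the p = 0 sentinel and counted in
#' `n_degenerate`).
#'
#' @param pos_table Output of [position_error_table()] (its `"total"`
#'   rows are ignored here).
#' @param groups Named vector mapping sample ids to the two group labels.
#' @param alpha Significance level on adjusted p-values (default 0.05).
#' @param correction `"bonferroni"` (within source-base family, default),
#'   `"bh"`, or `"none"`.
#' @return List with `hits` (significant rows with direction), `tested`
#'   (per source base: number of tested positions), `n_degenerate`, and
#'   the full `table` of tests.
#' @export
compare_positions <- function(pos_table, groups, alpha = 0.05,
                              correction = c("bonferroni", "bh", "none")) {
  correction <- match.arg(correction)
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2)
  g1 <- levels(groups)[1]; g2 <- levels(groups)[2]
  dt <- as.data.table(pos_table)[class != "total"]
  dt[, grp := groups[sample_id]]
  # per (position, class): Welch stats from group means/vars, vectorized
  agg <- dt[, .(n = .N, m = mean(rate), v = var(rate)),
            by = .(chrom, pos, ref_base, class, grp)]
  wide <- dcast(agg, chrom + pos + ref_base + class ~ grp,
                value.var = c("n", "m", "v"))
  n1c <- paste0("n_", g1); n2c <- paste0("n_", g2)
  m1c <- paste0("m_", g1); m2c <- paste0("m_", g2)
  v1c <- paste0("v_", g1); v2c <- paste0("v_", g2)
  wide <- wide[!is.na(get(n1c)) & !is.na(get(n2c)) &
                 get(n1c) >= 2 & get(n2c) >= 2]
  wide[, `:=`(m1 = get(m1c), m2 = get(m2c), v1 = get(v1c), v2 = get(v2c),
              n1 = get(n1c), n2 = get(n2c))]
  wide[, degenerate := v1 == 0 & v2 == 0]
  wide[, se2 := v1 / n1 + v2 / n2]
  wide[, t := fifelse(se2 > 0, (m1 - m2) / sqrt(se2),
                      fifelse(m1 == m2, 0, Inf * sign(m1 - m2)))]
  wide[, df := fifelse(se2 > 0,
                       se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
                       n1 + n2 - 2)]
  wide[, p := fifelse(se2 > 0, 2 * pt(-abs(t), df),
                      fifelse(m1 == m2, 1, 0))]
  # untestable: both groups constant-equal (all-zero positions in practice)
  testable <- wide[!(degenerate & m1 == m2)]
  n_degenerate <- nrow(wide[degenerate & m1 != m2])
  testable[, p_adj := switch(correction,
                             bonferroni = pmin(1, p * .N),
                             bh = p.adjust(p, "BH"),
                             none = p),
           by = ref_base]
  testable[, significant := p_adj < alpha]
  testable[, higher_group := fifelse(m1 > m2, g1, fifelse(m1 < m2, g2,
                                                          NA_character_))]
  tested <- testable[, .(n_tested = uniqueN(data.table(chrom, pos))),
                     by = ref_base]
  hits <- testable[significant == TRUE,
                   .(chrom, pos, ref_base, class, m1, m2, t, p, p_adj,
                     higher_group)]
  setnames(hits, c("m1", "m2"), c(paste0("mean_", g1), paste0("mean_", g2)))
  list(hits = hits, tested = tested, n_degenerate = n_degenerate,
       table = testable, groups = c(g1, g2), alpha = alpha,
       correction = correction)
}

#' Re-profile after excluding a set of positions
#'
#' The exclusion analysis: drop every position on a hit list, recompute
#' each sample's error profile on the complement, and report per-class and
#' total relative changes.
#'
#' @param hits `data.table` with `chrom`, `pos` (e.g. `$hits` from
#'   [compare_positions()]); may be empty.
#' @param counts_list Named list of `SiteCounts` tables.
#' @param masks One mask table or a named list parallel to `counts_list`.
#' @param filter A [filter_config()].
#' @param pair_of Optional named character vector mapping each sample id
#'   to its pair member's id for joint depth eligibility.
#' @param denominator Passed to [compute_error_profile()].
#' @return List with `profiles` (re-profiled), `deltas` (`data.table`:
#'   sample, class, rate before/after, relative change in percent).
#' @export
exclude_and_reprofile <- function(hits, counts_list, masks = NULL,
                                  filter = filter_config(), pair_of = NULL,
                                  denominator = "opportunity") {
  excl <- if (is.null(hits) || nrow(hits) == 0) NULL
          else unique(as.data.table(hits)[, .(chrom, pos)])
  run <- function(exclude) {
    out <- list()
    for (sid in names(counts_list)) {
      mask <- if (is.data.frame(masks)) masks else masks[[sid]]
      pc <- if (!is.null(pair_of) && !is.na(pair_of[sid]))
        counts_list[[pair_of[sid]]] else NULL
      out[[sid]] <- compute_error_profile(
        counts_list[[sid]], mask, filter, pair_counts = pc,
        sample_id = sid, exclude_positions = exclude,
        denominator = denominator)
    }
    out
  }
  before <- run(NULL)
  after <- run(excl)
  deltas <- rbindlist(lapply(names(before), function(sid) {
    b <- c(before[[sid]]$rates, total = before[[sid]]$total_rate)
    a <- c(after[[sid]]$rates, total = after[[sid]]$total_rate)
    data.table(sample_id = sid, class = c(SUBSTITUTION_CLASSES, "total"),
               rate_before = as.numeric(b), rate_after = as.numeric(a),
               change_pct = as.numeric(ifelse(!is.na(b) & b > 0,
                                              (a - b) / b * 100, NA_real_)))
  }))
  list(profiles = after, profiles_before = before, deltas = deltas,
       n_excluded = if (is.null(excl)) 0L else nrow(excl))
}

# two-proportion comparison of pooled error counts with different
# exposures; normal approximation on the rate difference under H0
pooled_rate_test <- function(k1, n1, k2, n2) {
  if (n1 == 0 || n2 == 0) return(NA_real_)
  p0 <- (k1 + k2) / (n1 + n2)
  if (p0 == 0 || p0 == 1) return(1)
  z <- (k1 / n1 - k2 / n2) / sqrt(p0 * (1 - p0) * (1 / n1 + 1 / n2))
  2 * stats::pnorm(-abs(z))
}

#' Contrast fragment-breakpoint bins within and between groups
#'
#' For each group: tests whether the total error rate in bin 1 (the 5 bp
#' adjacent to the breakpoint) exceeds the pooled rate of bins 2-10, and,
#' per class, bin 1 against bin 2. Counts are pooled over the group's
#' samples and compared as two binomial rates with their eligible-base
#' exposures (per-bin per-class counts are far too sparse at desk scale
#' for sample-level t-tests). Between groups, each class's bin-1 rate
#' difference is tested the same way. Bonferroni correction across the 12
#' classes within each test family.
#'
#' @param bin_profiles Named list of [fragment_bin_profile_obj()]s.
#' @param groups Named vector mapping sample ids to two group labels.
#' @param alpha Significance level on adjusted p-values (default 0.01).
#' @return List with `bin1_vs_rest` (per group, total rate),
#'   `bin1_vs_bin2` (per group x class), `between_groups` (per class,
#'   bin-1 rates), each a `data.table` with p and adjusted p.
#' @export
compare_bins <- function(bin_profiles, groups, alpha = 0.01) {
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2)
  pool <- function(ids) {
    cnt <- Reduce(`+`, lapply(ids, function(id) bin_profiles[[id]]$bin_counts))
    elig <- Reduce(`+`, lapply(ids, function(id) bin_profiles[[id]]$bin_eligible_bases))
    list(cnt = cnt, elig = elig)
  }
  lv <- levels(groups)
  pooled <- lapply(lv, function(g) pool(names(groups)[groups == g]))
  names(pooled) <- lv

  bin1_vs_rest <- rbindlist(lapply(lv, function(g) {
    cnt <- pooled[[g]]$cnt; elig <- pooled[[g]]$elig
    k1 <- sum(cnt[1, ]); n1 <- sum(elig[1, ])
    k2 <- sum(cnt[2:10, ]); n2 <- sum(elig[2:10, ])
    data.table(group = g, rate_bin1 = k1 / n1, rate_rest = k2 / n2,
               p = pooled_rate_test(k1, n1, k2, n2))
  }))
  bin1_vs_rest[, p_adj := p][, significant := p_adj < alpha]

  class_elig <- function(elig) elig[, class_ref(SUBSTITUTION_CLASSES)]
  bin1_vs_bin2 <- rbindlist(lapply(lv, function(g) {
    cnt <- pooled[[g]]$cnt; elig <- class_elig(pooled[[g]]$elig)
    rbindlist(lapply(seq_along(SUBSTITUTION_CLASSES), function(j) {
      data.table(group = g, class = SUBSTITUTION_CLASSES[j],
                 rate_bin1 = cnt[1, j] / elig[1, j],
                 rate_bin2 = cnt[2, j] / elig[2, j],
                 p = pooled_rate_test(cnt[1, j], elig[1, j],
                                      cnt[2, j], elig[2, j]))
    }))
  }))
  bin1_vs_bin2[, p_adj := pmin(1, p * 12), by = group]
  bin1_vs_bin2[, significant := !is.na(p_adj) & p_adj < alpha]

  bin1_vs_rest_class <- rbindlist(lapply(lv, function(g) {
    cnt <- pooled[[g]]$cnt; elig <- class_elig(pooled[[g]]$elig)
    rbindlist(lapply(seq_along(SUBSTITUTION_CLASSES), function(j) {
      k2 <- sum(cnt[2:10, j]); n2 <- sum(elig[2:10, j])
      data.table(group = g, class = SUBSTITUTION_CLASSES[j],
                 rate_bin1 = cnt[1, j] / elig[1, j],
                 rate_rest = k2 / n2,
                 p = pooled_rate_test(cnt[1, j], elig[1, j], k2, n2))
    }))
  }))
  bin1_vs_rest_class[, p_adj := pmin(1, p * 12), by = group]
  bin1_vs_rest_class[, significant := !is.na(p_adj) & p_adj < alpha]

  between <- rbindlist(lapply(seq_along(SUBSTITUTION_CLASSES), function(j) {
    c1 <- pooled[[lv[1]]]; c2 <- pooled[[lv[2]]]
    e1 <- class_elig(c1$elig); e2 <- class_elig(c2$elig)
    data.table(class = SUBSTITUTION_CLASSES[j],
               rate_1 = c1$cnt[1, j] / e1[1, j],
               rate_2 = c2$cnt[1, j] / e2[1, j],
               p = pooled_rate_test(c1$cnt[1, j], e1[1, j],
                                    c2$cnt[1, j], e2[1, j]))
  }))
  setnames(between, c("rate_1", "rate_2"),
           paste0("rate_bin1_", lv))
  between[, p_adj := pmin(1, p * 12)]
  between[, significant := !is.na(p_adj) & p_adj < alpha]

  list(bin1_vs_rest = bin1_vs_rest,
       bin1_vs_rest_class = bin1_vs_rest_class,
       bin1_vs_bin2 = bin1_vs_bin2,
       between_groups = between,
       groups = lv, alpha = alpha)
}

#' Concordance between duplicate runs
#'
#' For samples sequenced twice, compares the replicate-averaged class
#' rates: per class, the absolute difference between the mean rate of
#' replicate set 1 and replicate set 2.
#'
#' @param profiles Named list of [error_profile()]s.
#' @param replicate Named vector mapping sample ids to replicate labels
#'   (exactly two labels).
#' @return `data.table` with per-class mean rates of both replicate sets,
#'   `abs_diff`, and an attribute-free final row `"total"`; the maximum
#'   class difference is in `attr(, "max_abs_diff")`.
#' @export
replicate_concordance <- function(profiles, replicate) {
  replicate <- as.factor(replicate)
  if (nlevels(replicate) != 2)
    stop("replicate must have exactly two labels")
  lv <- levels(replicate)
  ids1 <- names(replicate)[replicate == lv[1]]
  ids2 <- names(replicate)[replicate == lv[2]]
  if (length(ids1) == 0 || length(ids2) == 0)
    stop("both replicate sets need at least one sample")
  m <- function(ids, cls)
    mean(vapply(ids, function(id) profiles[[id]]$rates[cls], numeric(1)))
  mt <- function(ids)
    mean(vapply(ids, function(id) profiles[[id]]$total_rate, numeric(1)))
  res <- rbindlist(lapply(SUBSTITUTION_CLASSES, function(cls) {
    a <- m(ids1, cls); b <- m(ids2, cls)
    data.table(class = cls, mean_rep1 = a, mean_rep2 = b,
               abs_diff = abs(a - b))
  }))
  res <- rbind(res, data.table(class = "total", mean_rep1 = mt(ids1),
                               mean_rep2 = mt(ids2),
                               abs_diff = abs(mt(ids1) - mt(ids2))))
  setattr(res, "max_abs_diff", max(res[class != "total"]$abs_diff))
  res[]
}
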