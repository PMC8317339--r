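mk_profile <- function(sid, rates, elig = 1e7) {
  eligv <- setNames(rep(elig / 4, 4), c("A", "C", "G", "T"))
  counts <- round(rates * eligv[substr(names(rates), 1, 1)])
  error_profile(sid, counts, eligv)
}

test_that("class-wise Welch tests match the closed-form arithmetic", {
  # fixed 3-vs-3 rate vectors, checked against stats::t.test
  x <- c(5.2e-5, 5.9e-5, 5.5e-5)
  y <- c(2.5e-5, 2.9e-5, 2.7e-5)
  profiles <- list()
  groups <- c()
  for (i in 1:3) {
    profiles[[paste0("cf_", i)]] <- mk_profile(paste0("cf_", i),
      setNames(rep(x[i] / 3, 12), SUBSTITUTION_CLASSES))
    profiles[[paste0("g_", i)]] <- mk_profile(paste0("g_", i),
      setNames(rep(y[i] / 3, 12), SUBSTITUTION_CLASSES))
    groups[paste0("cf_", i)] <- "cfDNA"
    groups[paste0("g_", i)] <- "gDNA"
  }
  cmp <- compare_class_rates(profiles, groups, alpha = 0.01)
  ref <- t.test(vapply(profiles[paste0("cf_", 1:3)], `[[`, numeric(1), "total_rate"),
                vapply(profiles[paste0("g_", 1:3)], `[[`, numeric(1), "total_rate"))
  expect_equal(cmp$total$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(cmp$total$p, ref$p.value, tolerance = 1e-10)
  # Bonferroni: adjusted p = min(1, 12 * p), total tested separately
  expect_equal(cmp$classes$p_adj, pmin(1, cmp$classes$p * 12))
  expect_true(all(cmp$classes[significant == TRUE]$higher_group == "cfDNA"))
})

test_that("identical groups produce no class hits", {
  profiles <- list()
  groups <- c()
  for (i in 1:3) {
    for (g in c("cf", "g")) {
      sid <- paste0(g, "_", i)
      profiles[[sid]] <- mk_profile(sid,
        setNames(rep(1e-5, 12), SUBSTITUTION_CLASSES))
      groups[sid] <- if (g == "cf") "cfDNA" else "gDNA"
    }
  }
  cmp <- compare_class_rates(profiles, groups)
  expect_false(any(cmp$classes$significant))
  expect_equal(cmp$total$p, 1)  # zero-variance equal means
  expect_error(compare_class_rates(profiles[c(1, 2)],
                                   groups[c(1, 2)]), "at least 2")
})

test_that("position tests equal a brute-force per-position loop", {
  fc <- filter_config(min_depth = 100L)
  set.seed(55)
  mk_ct <- function(t_counts) {
    data.table(chrom = "chr1", pos = 1:5, ref_base = "C", depth = 1000L,
               A = 0L, C = 1000L - t_counts, G = 0L, T = t_counts,
               key = c("chrom", "pos"))
  }
  counts <- list(cf_1 = mk_ct(c(9L, 0L, 1L, 2L, 0L)),
                 cf_2 = mk_ct(c(11L, 0L, 2L, 1L, 0L)),
                 cf_3 = mk_ct(c(10L, 1L, 0L, 3L, 0L)),
                 g_1 = mk_ct(c(0L, 0L, 1L, 2L, 0L)),
                 g_2 = mk_ct(c(1L, 0L, 2L, 3L, 0L)),
                 g_3 = mk_ct(c(0L, 1L, 1L, 1L, 0L)))
  groups <- setNames(rep(c("cfDNA", "gDNA"), each = 3), names(counts))
  tab <- position_error_table(counts, NULL, fc)
  res <- compare_positions(tab, groups, alpha = 0.05, correction = "none")
  # oracle: per position, plain Welch t-test on the per-sample rates
  for (pp in 1:4) {
    x <- vapply(counts[1:3], function(ct) ct[pos == pp]$T / 1000, numeric(1))
    y <- vapply(counts[4:6], function(ct) ct[pos == pp]$T / 1000, numeric(1))
    row <- res$table[pos == pp & class == "C>T"]
    if (var(x) == 0 && var(y) == 0) next
    ref <- t.test(x, y)
    expect_equal(row$p, ref$p.value, tolerance = 1e-10)
  }
  # position 5 is all-zero in both groups: untestable, not a hit
  expect_false(any(res$table[class == "C>T"]$pos == 5L))
  expect_false(any(res$hits$pos == 5L))
  # position 1 is a real difference
  expect_true(1L %in% res$hits$pos)
  expect_equal(res$hits[pos == 1L]$higher_group, "cfDNA")
})

test_that("an all-zero table yields no hits and no degenerate sentinels", {
  fc <- filter_config(min_depth = 100L)
  ct <- data.table(chrom = "chr1", pos = 1:4, ref_base = "A", depth = 500L,
                   A = 500L, C = 0L, G = 0L, T = 0L, key = c("chrom", "pos"))
  counts <- list(a1 = copy(ct), a2 = copy(ct), b1 = copy(ct), b2 = copy(ct))
  groups <- setNames(c("cfDNA", "cfDNA", "gDNA", "gDNA"), names(counts))
  res <- compare_positions(position_error_table(counts, NULL, fc), groups)
  expect_equal(nrow(res$hits), 0)
  expect_equal(res$n_degenerate, 0)
})

test_that("constant-but-different positions are flagged with the p=0 sentinel", {
  fc <- filter_config(min_depth = 100L)
  mk <- function(tc) data.table(chrom = "chr1", pos = 1L, ref_base = "C",
                                depth = 1000L, A = 0L, C = 1000L - tc, G = 0L,
                                T = tc, key = c("chrom", "pos"))
  counts <- list(a1 = mk(10L), a2 = mk(10L), b1 = mk(0L), b2 = mk(0L))
  groups <- setNames(c("cfDNA", "cfDNA", "gDNA", "gDNA"), names(counts))
  res <- compare_positions(position_error_table(counts, NULL, fc), groups)
  expect_equal(res$n_degenerate, 1)  # the constant-but-different C>T row
  expect_true(any(res$table$p == 0))
  expect_true(1L %in% res$hits$pos)
})

test_that("planted positional hotspots are recovered with correct direction", {
  set.seed(71)
  n_pos <- 1200L; depth <- 5000L; n_side <- 8L
  hot <- sort(sample.int(n_pos, 20))
  mk_ct <- function(hot_rate) {
    t_counts <- rbinom(n_pos, depth, 9e-6)
    t_counts[hot] <- t_counts[hot] + rbinom(20, depth, hot_rate)
    data.table(chrom = "chr1", pos = seq_len(n_pos), ref_base = "C",
               depth = depth, A = 0L, C = depth - t_counts, G = 0L,
               T = t_counts, key = c("chrom", "pos"))
  }
  counts <- c(
    setNames(lapply(1:n_side, function(i) mk_ct(5e-3)), paste0("cf_", 1:n_side)),
    setNames(lapply(1:n_side, function(i) mk_ct(0)), paste0("g_", 1:n_side)))
  groups <- setNames(rep(c("cfDNA", "gDNA"), each = n_side), names(counts))
  fc <- filter_config()
  tab <- position_error_table(counts, NULL, fc)
  res <- compare_positions(tab, groups, alpha = 0.05)
  found <- intersect(res$hits[class == "C>T"]$pos, hot)
  expect_gte(length(found), 18)
  expect_true(all(res$hits[pos %in% hot]$higher_group == "cfDNA"))
  # directionality invariant across all reported hits
  m1 <- paste0("mean_", res$groups[1])
  expect_true(all(res$hits[res$hits[[m1]] > res$hits[[paste0("mean_", res$groups[2])]],
                           higher_group] == res$groups[1]))
})

test_that("null positional tests are calibrated at uncorrected alpha", {
  set.seed(83)
  n_pos <- 400L; depth <- 2000L; reps <- 8L
  hits <- tested <- 0
  for (r in seq_len(reps)) {
    mk_ct <- function() {
      tc <- rbinom(n_pos, depth, 2e-3)
      data.table(chrom = "chr1", pos = seq_len(n_pos), ref_base = "C",
                 depth = depth, A = 0L, C = depth - tc, G = 0L, T = tc,
                 key = c("chrom", "pos"))
    }
    counts <- c(setNames(replicate(4, mk_ct(), simplify = FALSE), paste0("a", 1:4)),
                setNames(replicate(4, mk_ct(), simplify = FALSE), paste0("b", 1:4)))
    groups <- setNames(rep(c("cfDNA", "gDNA"), each = 4), names(counts))
    res <- compare_positions(position_error_table(counts, NULL,
                                                  filter_config()),
                             groups, alpha = 0.05, correction = "none")
    hits <- hits + nrow(res$table[class == "C>T" & significant == TRUE])
    tested <- tested + nrow(res$table[class == "C>T"])
  }
  # discrete rates make the t-test approximate; allow a generous band
  expect_gt(tested, 1500)
  expect_lt(abs(hits / tested - 0.05), 0.035)
})

test_that("excluding an empty hit list reproduces profiles exactly", {
  cfg <- sim_config(mode = "counts", seed = 61, panel_bp = 3000,
                    depth = 1000, n_pairs = 1)
  sim <- simulate_counts(cfg)
  fc <- filter_config()
  res <- exclude_and_reprofile(NULL, sim$counts, NULL, fc)
  expect_equal(res$n_excluded, 0)
  expect_true(all(res$deltas$change_pct == 0, na.rm = TRUE))
  expect_identical(res$profiles$cf_1$error_counts,
                   res$profiles_before$cf_1$error_counts)
  # excluding everything leaves undefined rates, reported missing
  all_pos <- sim$counts$cf_1[, .(chrom, pos)]
  res2 <- exclude_and_reprofile(all_pos, sim$counts, NULL, fc)
  expect_true(all(is.na(res2$deltas$rate_after)))
})

test_that("bin contrasts detect end damage and stay silent on flat bins", {
  mkbp <- function(sid, bin1_extra = 0) {
    cnt <- matrix(5, 10, 12)
    cnt[1, 2] <- cnt[1, 2] + bin1_extra  # C>A column index 2 in A-first order?
    elig <- matrix(5e5, 10, 4)
    fragment_bin_profile_obj(sid, cnt, elig)
  }
  # flat world: nothing significant
  profs <- list(a1 = mkbp("a1"), a2 = mkbp("a2"),
                b1 = mkbp("b1"), b2 = mkbp("b2"))
  groups <- setNames(rep(c("cfDNA", "gDNA"), each = 2), names(profs))
  cmp <- compare_bins(profs, groups)
  expect_false(any(cmp$bin1_vs_rest$significant))
  expect_false(any(cmp$bin1_vs_bin2$significant, na.rm = TRUE))
  # a strong bin-1 excess in one class of one group is found there only
  profs2 <- list(a1 = mkbp("a1"), a2 = mkbp("a2"),
                 b1 = mkbp("b1", 60), b2 = mkbp("b2", 60))
  cmp2 <- compare_bins(profs2, groups)
  cls <- SUBSTITUTION_CLASSES[2]
  sig <- cmp2$bin1_vs_rest_class[significant == TRUE]
  expect_equal(sig$group, "gDNA")
  expect_equal(sig$class, cls)
})

test_that("replicate concordance is zero for identical duplicates", {
  p1 <- mk_profile("s1", setNames(rep(1e-5, 12), SUBSTITUTION_CLASSES))
  p2 <- mk_profile("s2", setNames(rep(1e-5, 12), SUBSTITUTION_CLASSES))
  conc <- replicate_concordance(list(s1 = p1, s2 = p2),
                                c(s1 = "rep1", s2 = "rep2"))
  expect_true(all(conc$abs_diff == 0))
  expect_equal(attr(conc, "max_abs_diff"), 0)
  expect_error(replicate_concordance(list(s1 = p1), c(s1 = "rep1")),
               "two labels")
})

test_that("duplicate simulations agree within binomial sampling error", {
  fc <- filter_config()
  run_once <- function(seed) {
    sim <- simulate_counts(sim_config(mode = "counts", seed = seed,
                                      panel_bp = 20000, depth = 1000,
                                      n_pairs = 2))
    lapply(sim$counts[c("g_1", "g_2")], function(ct)
      compute_error_profile(ct, NULL, fc))
  }
  pr <- c(run_once(101), run_once(202))
  names(pr) <- paste0("d", 1:4)
  conc <- replicate_concordance(pr, c(d1 = "rep1", d2 = "rep1",
                                      d3 = "rep2", d4 = "rep2"))
  # each replicate mean uses ~1e7 eligible bases per reference base, so a
  # class difference has SD sqrt(2) * sqrt(r/1e7); bound the max over the
  # 12 classes at the ~99.9% level
  sd_diff <- sqrt(2) * sqrt(9e-6 / 1e7)
  expect_lt(attr(conc, "max_abs_diff"), 4 * sd_diff)
})
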